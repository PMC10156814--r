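# Unit conversions. Interfaces use clinical units (L/min, mmHg, rpm);
# all internal computation is SI.

LPM_TO_M3S <- 1 / 60000
MMHG_TO_PA <- 133.322
RPM_TO_RADS <- pi / 30
MM_TO_M <- 1e-3
GRAVITY <- 9.80665

lpm_to_m3s <- function(q) q * LPM_TO_M3S
mmhg_to_pa <- function(p) p * MMHG_TO_PA
pa_to_mmhg <- function(p) p / MMHG_TO_PA
rpm_to_rads <- function(w) w * RPM_TO_RADS

# cotangent of an angle given in degrees, exact at 90 (cot = 0)
cot_deg <- function(deg) cospi(deg / 180) / sinpi(deg / 180)

abort_validation <- function(msg) {
  rlang::abort(msg, class = "bladeforge_error_validation")
}
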