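# Internal unit system is CGS (dyn, cm, s, poise); the user-facing API speaks
# the field's units (mmHg, micrometres, nl/min, cP). All conversions live here.

MMHG_TO_DYN_CM2 <- 1333.22
UM_TO_CM <- 1e-4
NLMIN_TO_CM3S <- 1e-6 / 60
CP_TO_POISE <- 1e-2
DYN_CM2_TO_KPA <- 1e-4 # 1 dyn/cm^2 = 0.1 Pa

mmHg_to_cgs <- function(p) p * MMHG_TO_DYN_CM2
cgs_to_mmHg <- function(p) p / MMHG_TO_DYN_CM2
um_to_cm <- function(x) x * UM_TO_CM
nlmin_to_cgs <- function(q) q * NLMIN_TO_CM3S
cgs_to_nlmin <- function(q) q / NLMIN_TO_CM3S
cp_to_poise <- function(mu) mu * CP_TO_POISE

# hydraulic conductivity: nl/(min mmHg um^2) -> cm^3/(s (dyn/cm^2) cm^2)
k_to_cgs <- function(k) k * NLMIN_TO_CM3S / MMHG_TO_DYN_CM2 / UM_TO_CM^2
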