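# Versioned cohort presets for the synthetic phantom-cell generator.
#
# Provenance of each number:
#   study-derived : taken from the printed cohort statistics of the study the
#                   package emulates (apparent Young's modulus mean/sd for the
#                   M1 pair; the 1.53x / 1.69x cell-height fold decreases used
#                   to derive activated apex heights from the control apex).
#   assumed       : not printed anywhere; a declared modelling assumption
#                   (absolute control apex height, height log-sd, the
#                   power-law-exponent presets which encode only the printed
#                   *direction* of change, and the whole M2 modulus pair).
version: 1
presets:
  m1_control:
    label: "M1"
    ym_mean_kpa: 2.8      # study-derived
    ym_sd_kpa: 1.09       # study-derived
    alpha_mean: 0.25      # assumed (direction only)
    alpha_sd: 0.05        # assumed
    apex_um: 4.0          # assumed control apex height
    apex_sdlog: 0.08      # assumed
    cells: 25
  m1_pma:
    label: "M1+PMA"
    ym_mean_kpa: 6.92     # study-derived
    ym_sd_kpa: 2.87       # study-derived
    alpha_mean: 0.15      # assumed (direction only)
    alpha_sd: 0.05        # assumed
    apex_um: 2.614        # = 4.0 / 1.53, study-derived fold
    apex_sdlog: 0.08      # assumed
    cells: 25
  m2_control:
    label: "M2"
    ym_mean_kpa: 2.5      # assumed
    ym_sd_kpa: 1.0        # assumed
    alpha_mean: 0.25      # assumed (direction only)
    alpha_sd: 0.05        # assumed
    apex_um: 4.0          # assumed control apex height
    apex_sdlog: 0.08      # assumed
    cells: 20
  m2_pma:
    label: "M2+PMA"
    ym_mean_kpa: 4.5      # assumed
    ym_sd_kpa: 1.8        # assumed
    alpha_mean: 0.15      # assumed (direction only)
    alpha_sd: 0.05        # assumed
    apex_um: 2.367        # = 4.0 / 1.69, study-derived fold
    apex_sdlog: 0.08      # assumed
    cells: 20
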