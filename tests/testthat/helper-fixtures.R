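# Shared builders for small deterministic model configurations.

# The two active-system PTA4 change arms and the passive-system arm,
# as transcribed in the packaged study-summary fixture.
osia_pta4_arms <- function() {
  list(study_arm_summary("osia1", "pta4", 6, "change", 49, 27.90, 9.10),
       study_arm_summary("osia2", "pta4", 6, "change", 28, 28.40, 9.60))
}

baha_pta4_arm <- function() {
  study_arm_summary("baha1", "pta4", 6, "change", 54, 21.02, 10.41)
}

# Minimal arm: utility schedule and tariffs chosen for easy closed forms.
toy_arm <- function(name = "toy", baseline = 0.5, gain_3m = 0.2,
                    gain_6m = 0.3, monthly_reop = 0, monthly_ae = 0,
                    split = reoperation_split(0, 1, 0),
                    device = 1000, sp = 100, surgery = 10, hosp = 20,
                    ae_cost = 5) {
  arm_parameters(name,
                 cost_set(device, sp, surgery, hosp, ae_cost),
                 utility_schedule(baseline, gain_3m, gain_6m,
                                  se_baseline = 0, se_3m = 0, se_6m = 0),
                 monthly_reop, split, monthly_ae)
}

immortal_lt <- function() make_life_table("constant", q = 0)

toy_config <- function(start_age = 47, ...) {
  model_config(start_age = start_age, discount_annual = 0, ...)
}
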