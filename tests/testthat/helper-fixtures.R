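# Shared fixtures: reference truth, a standard residual-error model, the
# study sampling schedule, and small dataset builders used across tests.

ref_params <- fmn_reference_params()

prop_err <- function(sd = 0.2) {
  error_model("proportional", c(parent = sd, metabolite = sd))
}

add_err <- function(sd = 1) {
  error_model("additive", c(parent = sd, metabolite = sd))
}

study_schedule <- c(0.08, 0.16, 0.33, 0.5, 1, 2, 4, 8, 12, 24)
ref_dose <- 16529  # nmol; 20 mg/kg at the 0.2217 kg cohort-mean body weight

# Random valid parameter draw for property-style loops.
random_params <- function() {
  pk_params(
    F = runif(1, 0.1, 0.9), Fm = runif(1, 0.1, 0.95),
    ka = exp(runif(1, log(0.3), log(10))),
    V1 = exp(runif(1, log(5), log(60))),
    V2 = exp(runif(1, log(5), log(120))),
    Vm = exp(runif(1, log(2), log(40))),
    CL1 = exp(runif(1, log(2), log(60))),
    CL2 = exp(runif(1, log(2), log(80))),
    CLm = exp(runif(1, log(2), log(80)))
  )
}

# Minimal handwritten dataset: one subject, one dose row, two observations.
tiny_dataset <- function() {
  as_pk_dataset(tibble::tibble(
    ID = "r1", TIME = c(0, 0.5, 1), DVID = c(0L, 1L, 2L),
    DV = c(0, 50, 20), BLQ = 0L, AMT = c(16529, 0, 0), BW = 0.2217
  ))
}

# Noise-free dataset at the model curve (sigma = 0, no IIV).
noisefree_dataset <- function(n_subjects = 3, params = ref_params,
                              times = study_schedule) {
  rows <- purrr::map_dfr(seq_len(n_subjects), function(i) {
    sim <- pk_simulate(params, ref_dose, times)
    dplyr::bind_rows(
      tibble::tibble(ID = as.character(i), TIME = 0, DVID = 0L, DV = 0,
                     BLQ = 0L, AMT = ref_dose, BW = 0.2217),
      tibble::tibble(ID = as.character(i), TIME = rep(times, 2),
                     DVID = rep(c(1L, 2L), each = length(times)),
                     DV = c(sim$conc_parent, sim$conc_metabolite),
                     BLQ = 0L, AMT = 0, BW = 0.2217)
    )
  })
  as_pk_dataset(rows, lloq = c(parent = 1e-9, metabolite = 1e-9))
}

# Starting values at a multiple of truth (the recovery-protocol start).
start_at_multiple <- function(mult = 2, params = ref_params) {
  pk_params(
    F = params$F, Fm = params$Fm,
    ka = mult * params$ka, V1 = mult * params$V1, V2 = mult * params$V2,
    Vm = mult * params$Vm, CL1 = mult * params$CL1, CL2 = mult * params$CL2,
    CLm = mult * params$CLm
  )
}
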