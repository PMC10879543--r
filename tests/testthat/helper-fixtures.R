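# Fixture builders shared across test files. All fixtures are constructed in
# code; times sit on the 0.2-s coding grid.

toy_path <- function(file) {
  system.file("extdata", file, package = "dyadkit")
}

make_meta <- function(session_id = "T1", pnd = 10, nominal = 600,
                      caregiver_id = "M1", infant_id = "I1",
                      rearing = "family") {
  tibble::tibble(
    session_id = session_id, family_id = "F1", caregiver_id = caregiver_id,
    caregiver_role = "mother", infant_id = infant_id, infant_sex = "f",
    pnd = as.integer(pnd), rearing = rearing, assay = "retrieval",
    nominal_duration = nominal)
}

make_events <- function(session_id, ...) {
  rows <- list(...)
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(session_id = session_id, actor = r[[1]], behavior = r[[2]],
                   onset_s = as.numeric(r[[3]]), offset_s = as.numeric(r[[4]]))
  })
}

# The hand-computed reference session: retrieval 30, transport 30-50,
# holding 50-100, rejection 100-102, dismount 103, alone to 630.
fixture_session <- function(calls = NULL) {
  ev <- make_events(
    "T1",
    list("infant", "in_basket", 0, 30),
    list("caregiver", "retrieval", 30, 30.2),
    list("caregiver", "carry_contact", 30, 103),
    list("caregiver", "locomotion", 30, 50),
    list("caregiver", "rejection", 100, 102),
    list("infant", "dismount", 103, 103.2))
  build_session(make_meta("T1"), ev, calls)
}

# Session carried 580 s of a 630-s window with one 2-s rejection:
# pct_carry ~ 92.06, pct_rejection ~ 0.345.
fixture_session_carried580 <- function() {
  ev <- make_events(
    "T2",
    list("infant", "in_basket", 0, 30),
    list("caregiver", "retrieval", 30, 30.2),
    list("caregiver", "carry_contact", 30, 610),
    list("caregiver", "rejection", 100, 102),
    list("infant", "dismount", 610, 610.2))
  build_session(make_meta("T2"), ev)
}

random_session <- function(seed) {
  set.seed(seed)
  style <- caregiver_style(runif(1, 0.2, 1), runif(1, 0.05, 0.95),
                           runif(1, 0.3, 1))
  inf <- infant_state(sample(1:36, 1), avoidance_base = runif(1, 0, 0.5))
  simulate_session(style, inf, sim_config(), seed = seed + 10000L)$session
}
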