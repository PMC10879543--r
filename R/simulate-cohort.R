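# Cohort-level simulation: caregiver styles drawn once per caregiver and
# reused across infants and sessions; littermates share a birth id so that
# same-caregiver/different-infant (DI_SC) pairing is possible downstream.

#' Simulate a cohort of dyadic sessions
#'
#' Draws one latent style per caregiver (uniform sensitivity, tolerance and
#' carry motivation) and one avoidance baseline per infant, then simulates
#' every caregiver x infant x postnatal-day session. All randomness flows
#' from `seed` through per-session counters, so cohorts are reproducible
#' piecewise.
#'
#' @param n_families Number of families.
#' @param infants_per_birth Littermates per family (default 2, twins).
#' @param caregivers_per_family Caregivers per family (default 2: mother and
#'   father; a third is an older sibling).
#' @param pnd_schedule Postnatal days on which each dyad is assayed
#'   (default c(6, 13, 20, 27)).
#' @param config A `sim_config`.
#' @param seed Master seed.
#' @param art_infants Number of infants per family reared artificially
#'   (default 0); the first `art_infants` littermates of each family get the
#'   Art condition.
#' @param out_dir Optional directory; when given, writes `events.csv`,
#'   `calls.csv`, `meta.csv` and `truth.json` in the package's interchange
#'   formats.
#' @return List with tibbles `events`, `calls`, `meta`, and `truth` (list:
#'   `styles` per caregiver, `infants` per infant, `dismounts` with
#'   generating labels, `change_point_s`).
#' @export
simulate_cohort <- function(n_families = 7, infants_per_birth = 2,
                            caregivers_per_family = 2,
                            pnd_schedule = c(6, 13, 20, 27),
                            config = sim_config(), seed = 1,
                            art_infants = 0, out_dir = NULL) {
  stopifnot(n_families >= 1, infants_per_birth >= 1,
            caregivers_per_family >= 1)
  set.seed(derive_seed(seed, 0L))
  roles <- c("mother", "father", "sibling")

  styles <- list(); infants <- list()
  meta_rows <- list()
  for (f in seq_len(n_families)) {
    fam <- sprintf("F%02d", f)
    for (cgi in seq_len(caregivers_per_family)) {
      cid <- sprintf("%s_%s", fam, roles[min(cgi, 3)])
      styles[[cid]] <- caregiver_style(
        sensitivity = runif(1, 0.2, 1),
        tolerance = runif(1, 0.05, 0.95),
        carry_motivation = runif(1, 0.3, 1))
    }
    for (ii in seq_len(infants_per_birth)) {
      iid <- sprintf("%s_i%d", fam, ii)
      infants[[iid]] <- list(
        avoidance_base = min(0.6, max(0, rnorm(
          1, config$infant$avoidance_base_mean,
          config$infant$avoidance_base_sd))),
        rearing = if (ii <= art_infants) "artificial" else "family",
        sex = sample(c("m", "f"), 1),
        birth_id = sprintf("%s_b1", fam))
    }
  }

  events <- list(); calls <- list(); truths <- list()
  counter <- 0L
  for (f in seq_len(n_families)) {
    fam <- sprintf("F%02d", f)
    for (cgi in seq_len(caregivers_per_family)) {
      cid <- sprintf("%s_%s", fam, roles[min(cgi, 3)])
      for (ii in seq_len(infants_per_birth)) {
        iid <- sprintf("%s_i%d", fam, ii)
        inf0 <- infants[[iid]]
        for (pnd in pnd_schedule) {
          counter <- counter + 1L
          sid <- sprintf("%s_%s_p%02d", cid, sub("^.*_", "", iid), pnd)
          meta <- tibble(
            session_id = sid, family_id = fam, caregiver_id = cid,
            caregiver_role = roles[min(cgi, 3)], infant_id = iid,
            infant_sex = inf0$sex, pnd = as.integer(pnd),
            rearing = inf0$rearing, assay = "retrieval",
            nominal_duration = config$nominal_duration_s)
          ist <- infant_state(pnd, inf0$rearing, inf0$avoidance_base,
                              config$infant$anxiety_gain)
          ist <- simulate_art_condition(ist, config)
          sim <- simulate_session(styles[[cid]], ist, config,
                                  seed = derive_seed(seed, counter),
                                  meta = meta)
          events[[counter]] <- sim$session$events
          calls[[counter]] <- sim$session$calls
          meta_rows[[length(meta_rows) + 1L]] <- meta
          truths[[counter]] <- sim$truth$dismounts
        }
      }
    }
  }

  meta_tab <- bind_rows(meta_rows)
  meta_tab$birth_id <- vapply(meta_tab$infant_id,
                              function(i) infants[[i]]$birth_id, character(1))
  out <- list(
    events = bind_rows(events),
    calls = bind_rows(calls),
    meta = meta_tab,
    truth = list(
      styles = tibble(
        caregiver_id = names(styles),
        sensitivity = vapply(styles, `[[`, double(1), "sensitivity"),
        tolerance = vapply(styles, `[[`, double(1), "tolerance"),
        carry_motivation = vapply(styles, `[[`, double(1), "carry_motivation")),
      infants = tibble(
        infant_id = names(infants),
        avoidance_base = vapply(infants, `[[`, double(1), "avoidance_base"),
        rearing = vapply(infants, `[[`, character(1), "rearing"),
        birth_id = vapply(infants, `[[`, character(1), "birth_id")),
      dismounts = bind_rows(truths),
      change_point_s = config$forced_delay$max_s))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(out$events, file.path(out_dir, "events.csv"))
    readr::write_csv(out$calls, file.path(out_dir, "calls.csv"))
    readr::write_csv(out$meta, file.path(out_dir, "meta.csv"))
    jsonlite::write_json(
      lapply(out$truth, function(x) if (is.data.frame(x)) x else x),
      file.path(out_dir, "truth.json"), dataframe = "rows", auto_unbox = TRUE)
  }
  out
}
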