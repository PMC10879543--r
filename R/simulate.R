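# Generative simulator of caregiver-infant sessions. Each caregiver carries
# a latent style (sensitivity, tolerance, carry motivation) held constant
# across infants and sessions; infants respond with avoidance and
# context-dependent calling. The simulator emits pipeline-ready event/call
# tables plus ground truth for parameter-recovery tests.

#' Simulator configuration
#'
#' Loads the documented default parameters shipped with the package
#' (`inst/extdata/sim-defaults.yaml`) and applies overrides.
#'
#' @param ... Named overrides, nested lists merged over the defaults (e.g.
#'   `rejection = list(hazard_scale_per_s = 0.02)`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(...) {
  path <- system.file("extdata", "sim-defaults.yaml", package = "dyadkit")
  cfg <- yaml::read_yaml(path)
  overrides <- list(...)
  cfg <- modify_list_deep(cfg, overrides)
  validate_sim_config(cfg)
  structure(cfg, class = c("sim_config", "list"))
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

validate_sim_config <- function(cfg) {
  for (ctx in context_levels()) {
    mix <- unlist(cfg$calls$type_mix[[ctx]])
    if (is.null(mix) || any(mix < 0) || abs(sum(mix) - 1) > 1e-6) {
      abort(sprintf("Call type mix for %s must be non-negative and sum to 1.", ctx))
    }
  }
  for (nm in c("anxiety_mix", "caregiver_mix")) {
    mix <- unlist(cfg$calls[[nm]])
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-6) {
      abort(sprintf("%s must be non-negative and sum to 1.", nm))
    }
  }
  rates <- unlist(cfg$calls$rates_per_min)
  if (any(rates < 0)) abort("Call rates must be >= 0.")
  invisible(cfg)
}

#' Latent caregiver style
#'
#' @param sensitivity In (0, 1]; drives the retrieval hazard (fast
#'   retrievers are sensitive to infant distress calls).
#' @param tolerance In `[0, 1]`; 1 - tolerance drives the rejection hazard.
#' @param carry_motivation In `[0, 1]`; persistence of carrying
#'   (re-retrieval speed after a dismount).
#' @return A `caregiver_style` list.
#' @export
caregiver_style <- function(sensitivity, tolerance, carry_motivation) {
  stopifnot(sensitivity > 0, sensitivity <= 1,
            tolerance >= 0, tolerance <= 1,
            carry_motivation >= 0, carry_motivation <= 1)
  structure(list(sensitivity = sensitivity, tolerance = tolerance,
                 carry_motivation = carry_motivation),
            class = "caregiver_style")
}

#' Latent infant state
#'
#' @param pnd Postnatal day.
#' @param rearing `"family"` or `"artificial"`.
#' @param avoidance_base Baseline probability-scale avoidance drive in
#'   `[0, 1]`.
#' @param anxiety_gain Scales negative-call emission under intolerant
#'   carriers.
#' @return An `infant_state` list.
#' @export
infant_state <- function(pnd, rearing = "family", avoidance_base = 0.12,
                         anxiety_gain = 1.0) {
  stopifnot(pnd >= 0, rearing %in% c("family", "artificial"),
            avoidance_base >= 0, avoidance_base <= 1, anxiety_gain >= 0)
  structure(list(pnd = pnd, rearing = rearing,
                 avoidance_base = avoidance_base, anxiety_gain = anxiety_gain),
            class = "infant_state")
}

#' Apply the artificial-rearing condition to an infant state
#'
#' Family-reared infants are returned unchanged. Artificially reared
#' infants get a raised avoidance baseline and an alone-context call-rate
#' multiplier that grows past PND 30; their direct-transfer propensity in
#' reunions drops after PND 12 (consumed by [simulate_reunion_bins()]).
#'
#' @param infant An `infant_state`.
#' @param config A `sim_config`.
#' @return The (possibly modified) `infant_state`, with `alone_call_mult`
#'   and `direct_transfer_drop` fields set for artificial rearing.
#' @export
simulate_art_condition <- function(infant, config = sim_config()) {
  if (infant$rearing != "artificial") return(infant)
  a <- config$art
  infant$avoidance_base <- min(1, infant$avoidance_base + a$avoidance_boost)
  infant$alone_call_mult <- a$alone_call_mult_base +
    a$alone_call_slope_per_day * max(0, infant$pnd - 30)
  infant$direct_transfer_drop <- if (infant$pnd > a$direct_transfer_pnd) {
    a$direct_transfer_drop
  } else 0
  infant
}

sample_mix <- function(n, mix) {
  mix <- unlist(mix)
  sample(names(mix), n, replace = TRUE, prob = mix)
}

# Truncated exponential on [min_s, max_s] by inverse-cdf.
rtrunc_exp <- function(n, mean_s, min_s, max_s) {
  rate <- 1 / mean_s
  u <- runif(n)
  lo <- 1 - exp(-rate * min_s)
  hi <- 1 - exp(-rate * max_s)
  -log(1 - (lo + u * (hi - lo))) / rate
}

#' Simulate one retrieval-assay session
#'
#' Generates the behavioral event stream and calls of a single session.
#' Retrieval latency is exponential with rate proportional to caregiver
#' sensitivity (censored at the nominal duration); carrying alternates
#' Holding and Transport through a two-state dwell process; rejection bouts
#' arrive with hazard proportional to (1 - tolerance); each rejection forces
#' a dismount with a short truncated-exponential delay with probability
#' `forced_prob`; voluntary dismounts arrive at a low hazard scaled by
#' infant avoidance. Infant calls are a marked Poisson process with
#' context-dependent rate and type mix plus a negative-call anxiety stream
#' while carried, proportional to (1 - tolerance).
#'
#' @param style A `caregiver_style`.
#' @param infant An `infant_state` (artificial rearing should already have
#'   been applied via [simulate_art_condition()]).
#' @param config A `sim_config`.
#' @param seed Integer seed for this session.
#' @param meta Optional one-row metadata tibble; a minimal one is
#'   fabricated when omitted.
#' @return List with `session` (a `dyad_session`) and `truth` (list with
#'   the per-dismount truth labels, the style and the infant state).
#' @export
simulate_session <- function(style, infant, config = sim_config(), seed = 1,
                             meta = NULL) {
  stopifnot(inherits(style, "caregiver_style"), inherits(infant, "infant_state"))
  set.seed(seed)
  W0 <- config$nominal_duration_s
  sid <- if (is.null(meta)) sprintf("sim_%d", seed) else meta$session_id
  if (is.null(meta)) {
    meta <- tibble(
      session_id = sid, family_id = "simF", caregiver_id = "simC",
      caregiver_role = "mother", infant_id = "simI", infant_sex = "f",
      pnd = as.integer(infant$pnd), rearing = infant$rearing,
      assay = "retrieval", nominal_duration = W0)
  }

  ret_rate <- config$retrieval$base_rate_per_s * style$sensitivity
  ret <- snap_to_grid(rexp(1, ret_rate))
  events <- list()
  dismount_truth <- list()
  add_event <- function(actor, behavior, onset, offset) {
    events[[length(events) + 1L]] <<- tibble(
      session_id = sid, actor = actor, behavior = behavior,
      onset_s = onset, offset_s = offset)
  }

  avoidance <- infant$avoidance_base
  lam_rej <- config$rejection$hazard_scale_per_s * (1 - style$tolerance)
  lam_vol <- config$voluntary$base_hazard_per_s *
    (1 + config$voluntary$avoidance_gain * avoidance)
  re_rate <- config$retrieval$re_retrieval_base_rate_per_s *
    style$sensitivity * pmax(style$carry_motivation, 0.05)

  if (ret >= W0) {
    W <- W0
    add_event("infant", "in_basket", 0, W)
    retrieval_time <- NA_real_
  } else {
    W <- ret + W0
    retrieval_time <- ret
    if (ret > 0) add_event("infant", "in_basket", 0, ret)
    add_event("caregiver", "retrieval", ret, min(ret + BIN_WIDTH, W))
    t <- ret
    while (t < W) {
      ep <- simulate_carry_episode(t, W, lam_rej, lam_vol, style, config)
      if (ep$end > ep$start) {
        add_event("caregiver", "carry_contact", ep$start, ep$end)
        emit_locomotion(ep$start, ep$end, config, add_event)
        if (nrow(ep$rejections) > 0) {
          for (i in seq_len(nrow(ep$rejections))) {
            add_event("caregiver", "rejection",
                      ep$rejections$onset[i], ep$rejections$offset[i])
          }
        }
      }
      if (is.na(ep$dismount_time)) break # carried to window end
      add_event("infant", "dismount", ep$dismount_time,
                min(ep$dismount_time + BIN_WIDTH, W))
      dismount_truth[[length(dismount_truth) + 1L]] <- tibble(
        session_id = sid, time = ep$dismount_time, truth = ep$dismount_truth)
      gap <- rexp(1, re_rate)
      next_ret <- snap_to_grid(ep$dismount_time + gap)
      alone_end <- min(next_ret, W)
      emit_contacts(ep$dismount_time + BIN_WIDTH, alone_end, avoidance,
                    config, add_event)
      if (next_ret >= W) break
      if (next_ret <= ep$dismount_time) next_ret <- ep$dismount_time + BIN_WIDTH
      add_event("caregiver", "retrieval", next_ret, min(next_ret + BIN_WIDTH, W))
      t <- next_ret
    }
  }

  ev <- bind_rows(events)
  ev$onset_s <- snap_to_grid(ev$onset_s)
  ev$offset_s <- snap_to_grid(ev$offset_s)
  ev <- filter(ev, .data$offset_s > .data$onset_s)
  session0 <- build_session(meta, ev, calls = NULL)
  timeline <- segment_contexts(session0, offset_s = config$dismount_threshold_s)
  calls <- simulate_calls(sid, timeline, style, infant, config)
  session <- build_session(meta, ev, calls)

  truth_dm <- bind_rows(dismount_truth)
  if (nrow(truth_dm) == 0) {
    truth_dm <- tibble(session_id = character(), time = double(),
                       truth = character())
  }
  list(session = session,
       truth = list(dismounts = truth_dm, style = style, infant = infant,
                    change_point_s = config$forced_delay$max_s))
}

# One carrying episode starting at `start`; returns carry extent, rejection
# bouts and the dismount (time + truth label) if any before the window end.
simulate_carry_episode <- function(start, W, lam_rej, lam_vol, style, config) {
  t <- start
  rejections <- list()
  dismount_time <- NA_real_
  truth <- NA_character_
  repeat {
    t_rej <- if (lam_rej > 0) t + rexp(1, lam_rej) else Inf
    t_vol <- if (lam_vol > 0) t + rexp(1, lam_vol) else Inf
    if (min(t_rej, t_vol) >= W) break
    if (t_vol < t_rej) {
      dismount_time <- snap_to_grid(t_vol)
      if (dismount_time <= start) dismount_time <- start + BIN_WIDTH
      # stay strictly after the last rejection end so the measured
      # rejection-to-dismount interval is at least one coding bin
      last_off <- if (length(rejections)) max(vapply(rejections, `[[`,
                                                     double(1), "offset")) else -Inf
      if (dismount_time <= last_off) dismount_time <- last_off + BIN_WIDTH
      if (dismount_time >= W) { dismount_time <- NA_real_; truth <- NA_character_; break }
      truth <- "voluntary"
      break
    }
    r_on <- snap_to_grid(t_rej)
    d <- max(BIN_WIDTH, snap_to_grid(rexp(1, 1 / config$rejection$bout_mean_s)))
    r_off <- min(r_on + d, W)
    if (r_off <= r_on) break
    rejections[[length(rejections) + 1L]] <- tibble(onset = r_on, offset = r_off)
    if (r_off >= W) break
    if (runif(1) < config$rejection$forced_prob) {
      delay <- snap_to_grid(rtrunc_exp(1, config$forced_delay$mean_s,
                                       config$forced_delay$min_s,
                                       config$forced_delay$max_s))
      delay <- min(max(delay, BIN_WIDTH), config$forced_delay$max_s)
      dm <- r_off + delay
      if (dm < W) {
        dismount_time <- dm
        truth <- "forced"
      }
      break
    }
    t <- r_off
  }
  end <- if (is.na(dismount_time)) W else dismount_time
  rej_tab <- bind_rows(rejections)
  if (nrow(rej_tab) == 0) rej_tab <- tibble(onset = double(), offset = double())
  rej_tab <- filter(rej_tab, .data$onset < end)
  rej_tab$offset <- pmin(rej_tab$offset, end)
  list(start = start, end = end, rejections = rej_tab,
       dismount_time = dismount_time, dismount_truth = truth)
}

# Alternating stationary/locomoting dwells over a carry bout; emits
# caregiver locomotion intervals.
emit_locomotion <- function(start, end, config, add_event) {
  t <- start
  moving <- FALSE
  while (t < end) {
    dwell <- rexp(1, 1 / if (moving) config$carrying$transport_dwell_mean_s
                  else config$carrying$holding_dwell_mean_s)
    nxt <- min(end, snap_to_grid(t + max(dwell, BIN_WIDTH)))
    if (nxt <= t) nxt <- min(end, t + BIN_WIDTH)
    if (moving) add_event("caregiver", "locomotion", t, nxt)
    t <- nxt
    moving <- !moving
  }
}

# Caregiver contact bouts while the infant is alone; each is a cling
# opportunity the infant takes up with probability 1 - avoidance.
emit_contacts <- function(start, end, avoidance, config, add_event) {
  if (end - start < 1) return(invisible(NULL))
  n <- rpois(1, config$contact$rate_per_min * (end - start) / 60)
  if (n == 0) return(invisible(NULL))
  onsets <- snap_to_grid(sort(runif(n, start, end - 1)))
  for (on in onsets) {
    len <- max(1, snap_to_grid(rexp(1, 1 / config$contact$bout_mean_s)))
    off <- min(end, on + len)
    if (off <= on) next
    add_event("caregiver", "contact", on, off)
    if (runif(1) >= avoidance) {
      add_event("infant", "cling", on, min(on + BIN_WIDTH, off))
    }
  }
}

# Marked Poisson call process per context segment.
simulate_calls <- function(sid, timeline, style, infant, config) {
  cc <- config$calls
  alone_mult <- infant$alone_call_mult %||% 1
  anx_rate <- cc$anxiety_carried_rate_per_min * infant$anxiety_gain *
    (1 - style$tolerance)
  rows <- list()
  emit <- function(n, seg_start, seg_end, mix, caller = "infant") {
    if (n <= 0) return(invisible(NULL))
    onsets <- sort(runif(n, seg_start, seg_end))
    durs <- pmax(0.1, rexp(n, 1 / cc$call_duration_mean_s))
    rows[[length(rows) + 1L]] <<- tibble(
      session_id = sid, caller = caller,
      call_type = sample_mix(n, mix),
      onset_s = onsets, offset_s = pmin(onsets + durs, seg_end))
  }
  for (i in seq_len(nrow(timeline))) {
    ctx <- as.character(timeline$context[i])
    a <- timeline$start_s[i]; b <- timeline$end_s[i]
    mins <- (b - a) / 60
    rate <- cc$rates_per_min[[ctx]]
    if (ctx %in% c("Alone_BeforeRET", "Alone_AfterRET")) rate <- rate * alone_mult
    emit(rpois(1, rate * mins), a, b, cc$type_mix[[ctx]])
    if (ctx %in% c("Holding", "Transport") && anx_rate > 0) {
      emit(rpois(1, anx_rate * mins), a, b, cc$anxiety_mix)
    }
    if (cc$caregiver_rate_per_min > 0) {
      emit(rpois(1, cc$caregiver_rate_per_min * mins), a, b,
           cc$caregiver_mix, caller = "caregiver")
    }
  }
  out <- bind_rows(rows)
  if (length(rows) == 0 || nrow(out) == 0) return(empty_calls())
  arrange(out, .data$onset_s)
}

#' Simulate rejection-to-dismount intervals from the two-phase law
#'
#' Draws intervals directly from the generator's interval model: with
#' probability `p_forced` a forced delay (truncated exponential on
#' `(0, change_point]`), otherwise a voluntary interval (exponential with a
#' long mean, unconditioned, so a small fraction falls below the change
#' point as in real data). The change point of the log-survivorship curve
#' is the forced-delay support boundary.
#'
#' @param n Number of intervals.
#' @param config A `sim_config`; `forced_delay` governs the short phase.
#' @param p_forced Mixture weight of the forced phase (default 109/130, the
#'   observed below-threshold share among intervals).
#' @param voluntary_mean_s Mean of the voluntary interval law (default 110).
#' @return Numeric vector of intervals (seconds, 0.2-s grid, positive).
#' @export
simulate_dismount_intervals <- function(n, config = sim_config(),
                                        p_forced = 109 / 130,
                                        voluntary_mean_s = 110) {
  forced <- runif(n) < p_forced
  out <- numeric(n)
  nf <- sum(forced)
  if (nf > 0) {
    out[forced] <- rtrunc_exp(nf, config$forced_delay$mean_s,
                              config$forced_delay$min_s,
                              config$forced_delay$max_s)
  }
  if (nf < n) out[!forced] <- rexp(n - nf, 1 / voluntary_mean_s)
  pmax(snap_to_grid(out), BIN_WIDTH)
}

#' Simulate per-bin carrier identities for a family reunion
#'
#' Generates a one-zero-sampled carrier sequence: carriers hand the infant
#' over with per-bin probability `transfer_prob_per_bin`; a transfer is
#' direct with probability `direct_base - direct_pnd_slope_per_day * pnd`,
#' further reduced by the infant's artificial-rearing `direct_transfer_drop`;
#' nondirect transfers insert 1-3 not-carried bins.
#'
#' @param infant An `infant_state` (after [simulate_art_condition()]).
#' @param config A `sim_config`.
#' @param carriers Character vector of carrier ids to rotate through.
#' @param seed Integer seed.
#' @return Character vector of per-bin carrier ids with `"none"` for
#'   not-carried bins.
#' @export
simulate_reunion_bins <- function(infant, config = sim_config(),
                                  carriers = c("mother", "father", "sibling"),
                                  seed = 1) {
  set.seed(seed)
  ru <- config$reunion
  p_direct <- max(0, min(1, ru$direct_base -
                           ru$direct_pnd_slope_per_day * infant$pnd -
                           (infant$direct_transfer_drop %||% 0)))
  bins <- character(ru$n_bins)
  cur <- sample(carriers, 1)
  i <- 1L
  while (i <= ru$n_bins) {
    bins[i] <- cur
    if (runif(1) < ru$transfer_prob_per_bin) {
      nxt <- sample(setdiff(carriers, cur), 1)
      if (runif(1) >= p_direct) {
        n_gap <- sample(1:3, 1)
        gap_end <- min(ru$n_bins, i + n_gap)
        if (i < gap_end) {
          bins[(i + 1L):gap_end] <- "none"
          i <- gap_end
        }
      }
      cur <- nxt
    }
    i <- i + 1L
  }
  bins[bins == ""] <- cur
  bins
}
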