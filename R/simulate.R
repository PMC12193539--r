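#' Semi-Markov behavioral sequence generator
#'
#' A generator specification describes a phase-structured first-order chain
#' over behavioral acts: an initial distribution, a transition probability
#' matrix with a zero diagonal (no self-transitions, so simulated trials are
#' born repeat-collapsed), per-act stopping probabilities (1 for strictly
#' terminal acts; between 0 and 1 for acts at which some sequences end, e.g.
#' guarding held until the end of a bioassay), and a per-act duration model.
#'
#' @param acts character vector of codes.
#' @param initial named probability vector over `acts`, summing to 1.
#' @param transition `acts` x `acts` matrix; each row with stopping
#'   probability < 1 must sum to 1 (probabilities conditional on
#'   continuing); the diagonal must be zero.
#' @param stop_prob named vector of per-act stopping probabilities in
#'   `[0, 1]`; defaults to 1 for acts whose transition row is all zero
#'   (terminal acts) and 0 otherwise.
#' @param duration_model named list of per-act duration models, each a list
#'   with `family` (`"constant"`, `"lognormal"` or `"gamma"`) and its
#'   parameters (`value`; `mean` and `sdlog`; `shape` and `rate`), seconds.
#'   Acts without an entry default to lognormal with mean 10 s, sdlog 0.5.
#' @param n_trials default number of trials per simulation.
#' @param max_length safety bound on sequence length (default 200).
#' @param seed default random seed recorded on the spec.
#' @param sex,group labels stamped on simulated trials.
#' @return An object of class `ethochain_generator`.
#' @seealso [simulate_trials()], [spec_from_analysis()]
#' @export
generator_spec <- function(acts, initial, transition, stop_prob = NULL,
                           duration_model = NULL, n_trials = 1L,
                           max_length = 200L, seed = NULL,
                           sex = NA_character_, group = NA_character_) {
  acts <- as.character(acts)
  stopifnot(length(acts) >= 1L, !anyDuplicated(acts))
  if (n_trials < 1L) abort("`n_trials` must be >= 1", "usage_error")
  initial <- initial[acts]
  initial[is.na(initial)] <- 0
  names(initial) <- acts
  if (abs(sum(initial) - 1) > 1e-9) abort("initial distribution must sum to 1", "spec_error")
  transition <- transition[acts, acts, drop = FALSE]
  if (any(diag(transition) != 0)) abort("self-transitions are forbidden (nonzero diagonal)", "spec_error")
  if (any(transition < 0)) abort("negative transition probability", "spec_error")
  row_sums <- rowSums(transition)
  if (is.null(stop_prob)) {
    stop_prob <- ifelse(row_sums == 0, 1, 0)
    names(stop_prob) <- acts
  } else {
    stop_prob <- stop_prob[acts]
    stop_prob[is.na(stop_prob)] <- 0
    names(stop_prob) <- acts
  }
  if (any(stop_prob < 0 | stop_prob > 1)) abort("stopping probabilities must be in [0, 1]", "spec_error")
  bad <- stop_prob < 1 & abs(row_sums - 1) > 1e-9
  if (any(bad)) {
    abort(sprintf("non-terminal transition row(s) do not sum to 1: %s",
                  paste(acts[bad], collapse = ", ")), "spec_error")
  }
  structure(list(
    acts = acts, initial = initial, transition = transition,
    stop_prob = stop_prob, terminal_acts = acts[stop_prob == 1],
    duration_model = duration_model %||% list(),
    n_trials = as.integer(n_trials), max_length = as.integer(max_length),
    seed = seed, sex = sex, group = group
  ), class = "ethochain_generator")
}

#' @export
print.ethochain_generator <- function(x, ...) {
  cat(sprintf("<sequence generator: %d acts, %d terminal, n_trials = %d, max_length = %d>\n",
              length(x$acts), length(x$terminal_acts), x$n_trials, x$max_length))
  invisible(x)
}

draw_duration <- function(model) {
  if (is.null(model)) model <- list(family = "lognormal", mean = 10, sdlog = 0.5)
  switch(model$family,
    constant = model$value,
    lognormal = {
      sdlog <- model$sdlog %||% 0.5
      stats::rlnorm(1, meanlog = log(model$mean) - sdlog^2 / 2, sdlog = sdlog)
    },
    gamma = stats::rgamma(1, shape = model$shape, rate = model$rate),
    abort(sprintf("unknown duration family '%s'", model$family), "spec_error")
  )
}

#' Simulate trial collections from a generator
#'
#' Each trial starts from the initial distribution and steps through the
#' transition matrix; after each act the sequence ends with that act's
#' stopping probability (always, for terminal acts), or when `max_length`
#' is reached (the trial is then flagged `truncated`). Durations are drawn
#' from the per-act duration models. Fully reproducible from `seed`: one
#' seeded generator per call.
#'
#' @param spec an [generator_spec()].
#' @param n_trials number of trials; defaults to the spec's.
#' @param seed random seed; defaults to the spec's.
#' @return List of `ethochain_trial` objects (attribute `seed` records the
#'   seed used; trials hitting `max_length` carry attribute
#'   `truncated = TRUE`).
#' @export
simulate_trials <- function(spec, n_trials = spec$n_trials, seed = spec$seed) {
  stopifnot(inherits(spec, "ethochain_generator"))
  if (!is.null(seed)) set.seed(seed)
  acts <- spec$acts
  out <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    codes <- character(0)
    durations <- numeric(0)
    current <- sample(acts, 1L, prob = spec$initial)
    truncated <- FALSE
    repeat {
      codes <- c(codes, current)
      durations <- c(durations, draw_duration(spec$duration_model[[current]]))
      if (length(codes) >= spec$max_length) {
        truncated <- TRUE
        break
      }
      if (stats::runif(1) < spec$stop_prob[[current]]) break
      current <- sample(acts, 1L, prob = spec$transition[current, ])
    }
    tr <- trial(sprintf("sim%04d", i), codes, durations,
                sex = spec$sex, group = spec$group)
    if (truncated) attr(tr, "truncated") <- TRUE
    out[[i]] <- tr
  }
  attr(out, "seed") <- seed
  out
}

#' Derive a generator from an analysis or reference table
#'
#' Row-normalizes the observed transition counts into conditional
#' transition probabilities: P(a to b) = O(a, b) / row total(a). Acts with
#' no outgoing transitions become terminal. The initial distribution comes
#' from observed first acts when supplied; otherwise it is imputed from the
#' margins via net flow (an act entered less often than it is left must
#' start sequences; one entered more often than left must end them), which
#' also yields per-act stopping probabilities
#' ends(a) / visits(a).
#'
#' @param x an `ethochain_analysis`, `ethochain_fixture` or
#'   `ethochain_matrix`.
#' @param first_acts optional character vector of observed first acts (one
#'   per trial).
#' @param ... passed on to [generator_spec()] (e.g. `duration_model`,
#'   `n_trials`, `seed`).
#' @return An `ethochain_generator`.
#' @examples
#' fx <- load_reference_table("virgin_male")
#' gen <- spec_from_analysis(fx)
#' gen$transition["MTDF", "MWDF"]  # 1.0
#' @export
spec_from_analysis <- function(x, first_acts = NULL, ...) {
  UseMethod("spec_from_analysis")
}

#' @rdname spec_from_analysis
#' @export
spec_from_analysis.ethochain_matrix <- function(x, first_acts = NULL, ...) {
  acts <- unique(c(x$antecedents, x$subsequents))
  obs <- matrix(0, length(acts), length(acts), dimnames = list(acts, acts))
  obs[x$antecedents, x$subsequents] <- x$observed
  if (sum(obs) == 0) abort("empty matrix: no transitions to derive a generator from", "spec_error")
  out_tot <- rowSums(obs)
  in_tot <- colSums(obs)
  transition <- obs
  nonzero <- out_tot > 0
  transition[nonzero, ] <- obs[nonzero, , drop = FALSE] / out_tot[nonzero]

  if (!is.null(first_acts)) {
    init_counts <- table(factor(first_acts, levels = acts))
    if (sum(init_counts) == 0) abort("no usable first acts", "spec_error")
    initial <- as.numeric(init_counts) / sum(init_counts)
  } else {
    net <- pmax(out_tot - in_tot, 0)
    if (sum(net) == 0) net <- as.numeric(nonzero)  # fall back: uniform over non-terminal acts
    initial <- net / sum(net)
    init_counts <- net
  }
  names(initial) <- acts
  visits <- in_tot + as.numeric(init_counts)
  ends <- pmax(visits - out_tot, 0)
  stop_prob <- ifelse(visits > 0, ends / visits, 1)
  names(stop_prob) <- acts
  stop_prob[out_tot == 0] <- 1
  generator_spec(acts, initial, transition, stop_prob = stop_prob, ...)
}

#' @rdname spec_from_analysis
#' @export
spec_from_analysis.ethochain_analysis <- function(x, first_acts = NULL, ...) {
  spec_from_analysis(x$matrix, first_acts = first_acts, ...)
}

#' @rdname spec_from_analysis
#' @export
spec_from_analysis.ethochain_fixture <- function(x, first_acts = NULL, ...) {
  spec_from_analysis(fixture_matrix(x), first_acts = first_acts,
                     sex = x$sex, group = x$group, n_trials = x$n_trials, ...)
}

#' Generator presets for the four reference groups
#'
#' Convenience wrapper: derives the generator from the packaged reference
#' table of the given group, stamps the study's sample size as the default
#' `n_trials` (26 virgin / 15 once-mated couples), and attaches plausible
#' per-act lognormal duration means (the source reports no per-act duration
#' data, so these are placeholders: copulatory and guarding acts are long,
#' search and courtship acts short).
#'
#' @param group one of [reference_groups()].
#' @param ... passed on to [generator_spec()] (e.g. `n_trials`, `seed`).
#' @return An `ethochain_generator`.
#' @export
reference_generator <- function(group, ...) {
  fx <- load_reference_table(group)
  long_means <- c(MM = 300, MG = if (fx$group == "virgin_male") 387.5 else 219,
                  MIE = 20, FM = 240, FQHM = 120, FWP = 120, MWP = 120)
  durations <- lapply(unique(c(fx$antecedents, fx$subsequents)), function(code) {
    mean_s <- if (code %in% names(long_means)) long_means[[code]] else 15
    list(family = "lognormal", mean = mean_s, sdlog = 0.5)
  })
  names(durations) <- unique(c(fx$antecedents, fx$subsequents))
  spec_from_analysis(fx, duration_model = durations, ...)
}

#' Compare empirical transition frequencies to a generator
#'
#' For each non-terminal act, compares the empirical conditional transition
#' frequencies in `trials` to the generator's probabilities and reports the
#' per-row maximum absolute deviation along with the number of visits (rows
#' with fewer than `min_visits` visits are flagged `low_visits` rather than
#' being meaningful estimates).
#'
#' @param spec an `ethochain_generator`.
#' @param trials trials simulated from (or compared against) the spec.
#' @param min_visits visit count below which a row is flagged.
#' @return Data.frame with columns `act`, `visits`, `max_abs_error`,
#'   `low_visits`.
#' @export
recovery_report <- function(spec, trials, min_visits = 100L) {
  trials <- check_trials(trials)
  acts <- spec$acts
  obs <- matrix(0, length(acts), length(acts), dimnames = list(acts, acts))
  for (tr in trials) {
    codes <- tr$acts$code
    if (length(codes) < 2L) next
    tab <- table(factor(codes[-length(codes)], levels = acts),
                 factor(codes[-1L], levels = acts))
    obs <- obs + unclass(tab)
  }
  visits <- rowSums(obs)
  rows <- acts[spec$stop_prob < 1]
  max_err <- vapply(rows, function(a) {
    if (visits[[a]] == 0) return(NA_real_)
    max(abs(obs[a, ] / visits[[a]] - spec$transition[a, ]))
  }, numeric(1))
  data.frame(act = rows, visits = as.integer(visits[rows]),
             max_abs_error = unname(max_err),
             low_visits = visits[rows] < min_visits, row.names = NULL)
}

#' Fraction of strong generator edges recovered as significant
#'
#' Of the generator edges with conditional transition probability at least
#' `min_prob` (from non-terminal acts), the fraction flagged significant by
#' `analysis`. Used for the pipeline-closure check: analyzing sequences
#' simulated from a table-derived generator should recover the table's
#' strong edges.
#'
#' @param spec an `ethochain_generator`.
#' @param analysis an `ethochain_analysis` of trials simulated from `spec`.
#' @param min_prob conditional-probability cutoff defining a strong edge.
#' @return List with `recovered`, `total` and `fraction`.
#' @export
significant_edge_recovery <- function(spec, analysis, min_prob = 0.2) {
  rows <- spec$acts[spec$stop_prob < 1]
  idx <- which(spec$transition[rows, , drop = FALSE] >= min_prob, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list(recovered = 0L, total = 0L, fraction = NA_real_))
  from <- rows[idx[, 1L]]
  to <- spec$acts[idx[, 2L]]
  sig <- analysis$cells[analysis$cells$significant, , drop = FALSE]
  hit <- paste(from, to) %in% paste(sig$antecedent, sig$subsequent)
  list(recovered = sum(hit), total = length(hit), fraction = mean(hit))
}
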