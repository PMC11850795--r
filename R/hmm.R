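#' Construct a Gaussian hidden Markov model
#'
#' Builds a fixed (not fitted) K-state HMM with diagonal-covariance Gaussian
#' emissions. Mostly useful for simulation and for evaluating likelihoods
#' under known parameters; [fit_hmm()] returns the same class.
#'
#' @param means K x D matrix of emission means (rows = states).
#' @param variances K x D matrix of emission variances, all > 0.
#' @param A K x K transition matrix; rows must sum to 1.
#' @param pi initial state distribution of length K, sums to 1.
#' @param feature_names optional D feature names (defaults to the column
#'   names of `means`).
#' @param scaling optional per-feature scaling (tibble: `feature`, `mean`,
#'   `sd`) applied to raw data before evaluating emissions; identity when
#'   omitted.
#' @return an object of class `celltrax_hmm`.
#' @export
hmm_model <- function(means, variances, A, pi, feature_names = NULL, scaling = NULL) {
  means <- as.matrix(means); variances <- as.matrix(variances); A <- as.matrix(A)
  K <- nrow(means); D <- ncol(means)
  stopifnot(identical(dim(variances), dim(means)), nrow(A) == K, ncol(A) == K,
            length(pi) == K)
  if (any(variances <= 0)) {
    rlang::abort("variances must be > 0", class = "celltrax_parameter_error")
  }
  if (any(abs(rowSums(A) - 1) > 1e-9) || abs(sum(pi) - 1) > 1e-9 ||
      any(A < 0) || any(pi < 0)) {
    rlang::abort("rows of `A` and `pi` must be probability vectors",
                 class = "celltrax_parameter_error")
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(means) %||% paste0("feature", seq_len(D))
  }
  if (is.null(scaling)) {
    scaling <- tibble::tibble(feature = feature_names, mean = 0, sd = 1)
  }
  structure(
    list(K = K, D = D, means = unname(means), variances = unname(variances),
         A = unname(A), pi = as.numeric(pi), feature_names = feature_names,
         scaling = scaling, loglik = NA_real_, n_iter = NA_integer_,
         converged = NA, n_obs = NA_integer_, n_seq = NA_integer_,
         bic = NA_real_),
    class = "celltrax_hmm"
  )
}

#' @export
print.celltrax_hmm <- function(x, ...) {
  cat(sprintf("<celltrax_hmm> %d states on %s\n", x$K,
              paste(x$feature_names, collapse = ", ")))
  if (!is.na(x$loglik)) {
    cat(sprintf("  fitted on %d observations in %d sequence(s); loglik %.3f (BIC %.1f), %d iteration(s)%s\n",
                x$n_obs, x$n_seq, x$loglik, x$bic, x$n_iter,
                if (isTRUE(x$converged)) "" else " [not converged]"))
  }
  invisible(x)
}

# Split per-track feature series into contiguous finite runs: breaks at frame
# gaps (when `gap` exists) and at rows with non-finite features. Returns a
# list of numeric matrices plus bookkeeping to map rows back to the input.
#' @keywords internal
hmm_sequences <- function(steps, features, min_len = 2) {
  missing_feat <- setdiff(features, names(steps))
  if (length(missing_feat)) {
    rlang::abort(sprintf("feature column(s) absent: %s",
                         paste(missing_feat, collapse = ", ")),
                 class = "celltrax_schema_error")
  }
  ord <- order(steps$track_id, if ("frame" %in% names(steps)) steps$frame else
    seq_len(nrow(steps)))
  steps <- steps[ord, , drop = FALSE]
  x <- as.matrix(steps[features])
  gap <- if ("gap" %in% names(steps)) steps$gap else rep(FALSE, nrow(steps))
  # gap-spanning steps are dropped (their features straddle missing frames)
  ok <- apply(is.finite(x), 1, all) & !gap
  new_track <- c(TRUE, steps$track_id[-1] != steps$track_id[-nrow(steps)])
  run_start <- new_track | !ok | c(FALSE, !ok[-length(ok)])
  run_id <- cumsum(run_start)
  keep <- ok
  runs <- split(which(keep), run_id[keep])
  runs <- runs[vapply(runs, length, integer(1)) >= min_len]
  if (length(runs) == 0) {
    rlang::abort("no usable sequences (all shorter than 2 after gap/NA splitting)",
                 class = "celltrax_input_error")
  }
  list(
    x = x,
    runs = unname(runs),
    track_id = steps$track_id,
    frame = if ("frame" %in% names(steps)) steps$frame else rep(NA_integer_, nrow(steps)),
    order = ord
  )
}

#' @keywords internal
hmm_logdens <- function(x, model) {
  sc <- model$scaling
  xs <- sweep(sweep(x, 2, sc$mean, `-`), 2, sc$sd, `/`)
  ld <- matrix(0, nrow(xs), model$K)
  for (k in seq_len(model$K)) {
    ld[, k] <- rowSums(vapply(seq_len(model$D), function(j) {
      stats::dnorm(xs[, j], model$means[k, j], sqrt(model$variances[k, j]), log = TRUE)
    }, numeric(nrow(xs))))
  }
  ld
}

#' Fit a Gaussian HMM to pooled step-feature sequences
#'
#' Fits one shared K-state diagonal-Gaussian HMM to all tracks of a dataset
#' by Baum-Welch expectation-maximisation, then leaves decoding per track to
#' [decode_states()]. Features are z-scored over the pooled steps and the
#' scaling is stored in the model so decoding applies the identical
#' transform. Sequences are split at frame gaps and non-finite feature
#' values (e.g. the undefined turning angle at a track start); pieces
#' shorter than 2 observations are excluded. The best of `n_restarts`
#' seeded initialisations by final log-likelihood is returned, with states
#' relabelled in ascending order of the first feature's emission mean so
#' that identical data and seed always give the identical model. The EM
#' log-likelihood is asserted non-decreasing at every iteration.
#'
#' @param steps a tibble of per-step observations with `track_id`, optional
#'   `frame` and `gap`, and the feature columns (typically the output of
#'   [step_features()]).
#' @param features character vector of feature column names; default
#'   speed and turning angle, the classic motility pair.
#' @param K number of hidden states, >= 1 (K = 1 is allowed with a warning
#'   and reduces to sample moments).
#' @param n_restarts number of seeded EM restarts.
#' @param seed integer seed; restart r uses `seed + r - 1`.
#' @param max_iter,tol EM stopping rule: at most `max_iter` iterations or
#'   absolute log-likelihood improvement below `tol`.
#' @param log_speed if `TRUE`, `log(v + 1)` is applied to the `speed`
#'   feature before scaling (speeds are non-negative and right-skewed).
#' @param var_floor lower bound on emission variances (on the z-scored
#'   scale), guarding against collapse onto single points.
#' @return a fitted [hmm_model()] (class `celltrax_hmm`).
#' @export
fit_hmm <- function(steps, features = c("speed", "turning_angle"), K = 3,
                    n_restarts = 5, seed = 1, max_iter = 500, tol = 1e-4,
                    log_speed = FALSE, var_floor = 1e-4) {
  check_number(K, "K", 1)
  check_number(n_restarts, "n_restarts", 1)
  if (K == 1) rlang::warn("K = 1 is degenerate: a single Gaussian state")
  seqs <- hmm_sequences(steps, features)
  x <- seqs$x
  if (log_speed && "speed" %in% features) {
    x[, features == "speed"] <- log1p(x[, features == "speed"])
  }
  rows <- unlist(seqs$runs)
  mu <- colMeans(x[rows, , drop = FALSE])
  sd0 <- apply(x[rows, , drop = FALSE], 2, stats::sd)
  sd0[!is.finite(sd0) | sd0 < 1e-12] <- 1
  scaling <- tibble::tibble(feature = features, mean = unname(mu), sd = unname(sd0))
  xs <- sweep(sweep(x, 2, mu, `-`), 2, sd0, `/`)
  starts <- cumsum(c(0, vapply(seqs$runs, length, integer(1))))[seq_along(seqs$runs)]
  lengths <- vapply(seqs$runs, length, integer(1))
  obs <- xs[rows, , drop = FALSE]
  n_obs <- nrow(obs); D <- length(features)

  run_em <- function(rs) {
    set.seed(rs)
    pick <- sample(n_obs, K)
    means <- obs[pick, , drop = FALSE]
    vars <- matrix(1, K, D)
    A <- matrix(0.2 / max(1, K - 1), K, K); diag(A) <- if (K > 1) 0.8 else 1
    pi <- rep(1 / K, K)
    ll_prev <- -Inf; ll <- NA_real_; it <- 0; converged <- FALSE
    repeat {
      it <- it + 1
      ld <- matrix(0, n_obs, K)
      for (k in seq_len(K)) {
        ld[, k] <- rowSums(vapply(seq_len(D), function(j) {
          stats::dnorm(obs[, j], means[k, j], sqrt(vars[k, j]), log = TRUE)
        }, numeric(n_obs)))
      }
      es <- hmm_estep_cpp(ld, as.integer(starts), as.integer(lengths), A, pi)
      ll <- es$loglik
      if (ll < ll_prev - 1e-6 * (1 + abs(ll_prev))) {
        rlang::abort(sprintf("EM log-likelihood decreased (%.10g -> %.10g)", ll_prev, ll),
                     class = "celltrax_internal_error")
      }
      g <- es$gamma
      wk <- colSums(g)
      means <- matrix(vapply(seq_len(K), function(k) colSums(g[, k] * obs) / wk[k],
                             numeric(D)), nrow = K, ncol = D, byrow = TRUE)
      vars <- matrix(vapply(seq_len(K), function(k) {
        pmax(colSums(g[, k] * sweep(obs, 2, means[k, ], `-`)^2) / wk[k], var_floor)
      }, numeric(D)), nrow = K, ncol = D, byrow = TRUE)
      if (K > 1) {
        A <- es$xi_sum / pmax(rowSums(es$xi_sum), .Machine$double.eps)
        pi <- es$pi_sum / sum(es$pi_sum)
      }
      if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) { converged <- TRUE; break }
      if (it >= max_iter) break
      ll_prev <- ll
    }
    list(means = means, vars = vars, A = A, pi = pi, loglik = ll,
         n_iter = it, converged = converged)
  }

  fits <- lapply(seq_len(n_restarts), function(r) run_em(seed + r - 1))
  best <- fits[[which.max(vapply(fits, function(f) f$loglik, numeric(1)))]]
  perm <- order(best$means[, 1])
  model <- hmm_model(
    means = best$means[perm, , drop = FALSE],
    variances = best$vars[perm, , drop = FALSE],
    A = best$A[perm, perm, drop = FALSE],
    pi = best$pi[perm],
    feature_names = features,
    scaling = scaling
  )
  model$loglik <- best$loglik
  model$n_iter <- best$n_iter
  model$converged <- best$converged
  model$n_obs <- n_obs
  model$n_seq <- length(lengths)
  n_par <- K * D * 2 + K * (K - 1) + (K - 1)
  model$bic <- -2 * best$loglik + n_par * log(n_obs)
  model$log_speed <- log_speed
  model
}

#' Forward log-likelihood of a sequence under an HMM
#'
#' Evaluates the exact marginal log-likelihood of one observation sequence
#' by the scaled forward algorithm (summing over all hidden-state paths).
#'
#' @param model a `celltrax_hmm`.
#' @param x numeric matrix (T x D, columns in `model$feature_names` order)
#'   or vector for D = 1, on the raw feature scale.
#' @return a single number.
#' @export
hmm_loglik <- function(model, x) {
  stopifnot(inherits(model, "celltrax_hmm"))
  x <- as.matrix(x)
  stopifnot(ncol(x) == model$D)
  ld <- hmm_logdens(x, model)
  es <- hmm_estep_cpp(ld, 0L, nrow(ld), model$A, model$pi)
  es$loglik
}

#' Viterbi decoding of behaviour states
#'
#' Assigns every usable step its most probable hidden state by per-sequence
#' Viterbi decoding (ties between equally probable paths resolve to the
#' lowest state index), then summarises each track by its state occupancy
#' (fraction of steps per state, sums to 1) and its observed
#' state-transition frequencies (transition counts between consecutive
#' decoded states, normalised by the number of observed consecutive pairs).
#'
#' @param model a fitted `celltrax_hmm`.
#' @param steps the step tibble to decode; must contain all of
#'   `model$feature_names`.
#' @return an object of class `state_annotation`: list with `states`
#'   (tibble: `track_id`, `frame`, `hmm_state`), `occupancy` (tibble:
#'   `track_id`, `occ_1..K`) and `transitions` (tibble: `track_id`,
#'   `trans_<j>_<k>` columns).
#' @export
decode_states <- function(model, steps) {
  stopifnot(inherits(model, "celltrax_hmm"))
  seqs <- hmm_sequences(steps, model$feature_names)
  x <- seqs$x
  if (isTRUE(model$log_speed) && "speed" %in% model$feature_names) {
    x[, model$feature_names == "speed"] <- log1p(x[, model$feature_names == "speed"])
  }
  ld_all <- hmm_logdens(x, model)
  K <- model$K
  state <- rep(NA_integer_, nrow(x))
  for (run in seqs$runs) {
    v <- hmm_viterbi_cpp(ld_all[run, , drop = FALSE], model$A, model$pi)
    state[run] <- v$path
  }
  decoded <- tibble::tibble(
    track_id = seqs$track_id,
    frame = seqs$frame,
    hmm_state = state
  )[!is.na(state), ]
  # per-track occupancy
  occ <- decoded |>
    dplyr::count(.data$track_id, .data$hmm_state) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(occ = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(names_from = "hmm_state", values_from = "occ",
                       names_prefix = "occ_", values_fill = 0)
  for (k in seq_len(K)) {
    nm <- paste0("occ_", k)
    if (!nm %in% names(occ)) occ[[nm]] <- 0
  }
  occ <- occ[c("track_id", paste0("occ_", seq_len(K)))]
  # per-track transition frequencies from consecutive pairs within runs
  pair_rows <- do.call(rbind, lapply(seqs$runs, function(run) {
    if (length(run) < 2) return(NULL)
    cbind(from = run[-length(run)], to = run[-1])
  }))
  trans <- tibble::tibble(
    track_id = seqs$track_id[pair_rows[, 1]],
    from = state[pair_rows[, 1]],
    to = state[pair_rows[, 2]]
  ) |>
    dplyr::count(.data$track_id, .data$from, .data$to) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(col = paste0("trans_", .data$from, "_", .data$to)) |>
    dplyr::select("track_id", "col", "freq") |>
    tidyr::pivot_wider(names_from = "col", values_from = "freq", values_fill = 0)
  all_trans <- as.vector(outer(seq_len(K), seq_len(K),
                               function(j, k) paste0("trans_", j, "_", k)))
  for (nm in all_trans) if (!nm %in% names(trans)) trans[[nm]] <- 0
  trans <- trans[c("track_id", sort(all_trans))]
  # tracks with only length-1 runs have occupancy but no transitions: give
  # them an all-zero transition row so downstream joins keep them
  missing_tr <- setdiff(occ$track_id, trans$track_id)
  if (length(missing_tr)) {
    pad <- tibble::as_tibble(c(list(track_id = missing_tr),
                               stats::setNames(rep(list(0), length(all_trans)),
                                               sort(all_trans))))
    trans <- dplyr::bind_rows(trans, pad) |> dplyr::arrange(.data$track_id)
  }
  structure(list(states = decoded, occupancy = occ, transitions = trans, K = K),
            class = "state_annotation")
}

#' @export
print.state_annotation <- function(x, ...) {
  cat(sprintf("<state_annotation> %d decoded steps, %d track(s), %d states\n",
              nrow(x$states), nrow(x$occupancy), x$K))
  invisible(x)
}

#' Fit the 4-state shape-behaviour HMM
#'
#' Convenience wrapper fitting a hidden-Markov model on morphological
#' descriptors over time — asphericity, prolateness, shape anisotropy
#' kappa^2 and volume — with a default of four shape states, and decoding
#' the fitted model on the same steps.
#'
#' @param steps step tibble carrying the shape-descriptor columns.
#' @param K number of shape states (default 4).
#' @param features shape feature columns.
#' @param ... passed to [fit_hmm()].
#' @return list with `model` (`celltrax_hmm`) and `annotation`
#'   (`state_annotation`).
#' @export
fit_shape_hmm <- function(steps, K = 4,
                          features = c("asphericity", "prolateness", "kappa_sq", "volume"),
                          ...) {
  model <- fit_hmm(steps, features = features, K = K, ...)
  list(model = model, annotation = decode_states(model, steps))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted behaviour HMM
#'
#' @param x a `celltrax_hmm`.
#' @param ... unused.
#' @return a tibble with one row per state x feature: emission `mean` and
#'   `variance` (on the z-scored scale) plus the state's self-transition
#'   probability and stationary weight of the initial distribution.
#' @export
tidy.celltrax_hmm <- function(x, ...) {
  tidyr::expand_grid(state = seq_len(x$K), feature = x$feature_names) |>
    dplyr::mutate(
      mean = as.vector(t(x$means)),
      variance = as.vector(t(x$variances)),
      self_transition = rep(diag(x$A), each = x$D),
      initial_prob = rep(x$pi, each = x$D)
    )
}

#' @rdname tidy.celltrax_hmm
#' @return for `glance()`: a one-row tibble with `K`, `n_features`,
#'   `n_obs`, `n_seq`, `loglik`, `BIC`, `n_iter`, `converged`.
#' @export
glance.celltrax_hmm <- function(x, ...) {
  tibble::tibble(K = x$K, n_features = x$D, n_obs = x$n_obs, n_seq = x$n_seq,
                 loglik = x$loglik, BIC = x$bic, n_iter = x$n_iter,
                 converged = x$converged)
}
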