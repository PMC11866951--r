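#' Random train/test partitions of an occurrence set
#'
#' @param occ An [occurrence_set()] (>= 8 records).
#' @param train_frac Training fraction; train size is
#'   `round(train_frac * n)` (default 0.75, so 73 records split 55/18).
#' @param repeats Number of independent splits (default 10).
#' @param seed Integer seed; splits are reproducible.
#' @return List of `repeats` lists with integer index vectors `train`, `test`.
#' @export
partition_occurrences <- function(occ, train_frac = 0.75, repeats = 10,
                                  seed = NULL) {
  n <- nrow(occ)
  if (n < 8L) stop("need at least 8 occurrences to partition")
  n_train <- round(train_frac * n)
  if (n_train < 1L || n_train >= n) {
    stop("train_frac leaves an empty train or test set")
  }
  with_seed(seed, {
    lapply(seq_len(repeats), function(r) {
      tr <- sort(sample.int(n, n_train))
      list(train = tr, test = setdiff(seq_len(n), tr))
    })
  })
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The fraction of (presence, background) score pairs in which the presence
#' scores higher, ties counted one half — computed via midranks, identical to
#' exhaustive pair counting.
#'
#' @param presence_scores,background_scores Non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.9, 0.8), c(0.7, 0.6, 0.1))  # 1
#' auc(c(0.8, 0.4), c(0.8, 0.3, 0.1))  # 0.75
#' @export
auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores)
  nb <- length(background_scores)
  if (np == 0L || nb == 0L) stop("both score vectors must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Ten percent training omission rate
#'
#' The suitability threshold is the training score that excludes the lowest
#' 10\% of training presences (ceiling rank: with `n` training scores, the
#' `ceiling(0.1 n)` lowest are excluded and the threshold is the next order
#' statistic). The omission rate is the fraction of test presences scoring
#' strictly below that threshold; a test score equal to the threshold is not
#' omitted.
#'
#' @param train_scores Numeric vector (>= 10 values).
#' @param test_scores Non-empty numeric vector.
#' @return Omission rate in `[0, 1]`.
#' @export
omission10 <- function(train_scores, test_scores) {
  n <- length(train_scores)
  if (n < 10L) stop("need at least 10 training scores")
  if (length(test_scores) == 0L) stop("test scores must be non-empty")
  k <- ceiling(0.1 * n)
  thr <- sort(train_scores)[min(k + 1L, n)]
  mean(test_scores < thr)
}

#' Small-sample corrected AIC of a fitted maxent model
#'
#' Uses the raw output renormalized over \emph{all} valid landscape cells as
#' the likelihood (the ENMeval / Warren-Seifert convention): with `k` the
#' number of features with nonzero coefficients and `n` the number of
#' occurrence records,
#' `AICc = 2k - 2 ln L + 2k(k + 1) / (n - k - 1)`,
#' undefined (`NA`) when `k >= n - 1`.
#'
#' @param model A fitted [maxent()] model.
#' @param occ The occurrence set the model was fitted on.
#' @param stack The [env_stack()] defining the landscape.
#' @return AICc, or `NA_real_` when undefined.
#' @export
aicc <- function(model, occ, stack) {
  k <- sum(model$coefficients != 0)
  n <- nrow(occ)
  if (k >= n - 1) return(NA_real_)
  sv <- stack_values(stack, model$feature_spec$variables)
  eta_land <- maxent_eta(model, sv$values)
  m <- max(eta_land)
  logZ_land <- m + log(sum(exp(eta_land - m)))
  idx <- occ_cells(occ, stack)
  eta_occ <- maxent_eta(model, extract_cells(stack, idx$row, idx$col,
                                             model$feature_spec$variables))
  lnL <- sum(eta_occ - logZ_land)
  2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
}

# AICc from precomputed linear predictors (internal fast path for tuning)
aicc_from_eta <- function(eta_occ, eta_land, k) {
  n <- length(eta_occ)
  if (k >= n - 1) return(NA_real_)
  m <- max(eta_land)
  logZ_land <- m + log(sum(exp(eta_land - m)))
  lnL <- sum(eta_occ - logZ_land)
  2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
}

# deterministic candidate selection: min AICc, ties broken by smaller RM
# then shorter FC string then alphabetically
select_candidate <- function(results) {
  ok <- which(!is.na(results$aicc))
  if (length(ok) == 0L) stop("AICc undefined for every candidate")
  ord <- ok[order(results$aicc[ok], results$rm[ok],
                  nchar(results$fc[ok]), results$fc[ok])]
  ord[1]
}

#' Tune a maxent model over a regularization x feature-class grid
#'
#' Runs the candidate grid (default: RM in 0.5-4.0 by 0.5 crossed with FC in
#' {L, LQ, H, LQH, LQHP, LQHPT} — 48 candidates). Each candidate is fitted on
#' the full occurrence set for AICc (likelihood normalized over the
#' landscape) and refitted on each train/test partition for AUC and the 10\%
#' omission rate. The candidate with the minimum AICc is selected
#' (`delta_aicc = 0`); ties go to the smaller RM, then the shorter FC string.
#'
#' @param occ A cleaned [occurrence_set()].
#' @param stack An [env_stack()].
#' @param variables Variables to model (default all layers).
#' @param rms Regularization multipliers (default `seq(0.5, 4, by = 0.5)`).
#' @param fcs Feature-class strings (default the six standard combinations).
#' @param background Optional background [occurrence_set()]; defaults to
#'   [sample_background()] with `n_background` cells.
#' @param n_background Background size (default 1000).
#' @param n_knots Hinge/threshold knots per variable.
#' @param train_frac,repeats Partitioning controls (default 0.75, 10).
#' @param seed Integer seed driving background sampling and partitioning.
#' @param tol,max_iter Solver controls, as in [maxent()].
#' @param progress Print one line per candidate.
#' @return An object of class `enm_tuning`: list with `results` (one row per
#'   candidate: rm, fc, n_features, n_active, auc_train_avg, auc_test_avg,
#'   auc_diff_avg, auc_diff_sd, or10_avg, aicc, delta_aicc, selected),
#'   `selected` (row of the chosen candidate), and the call parameters.
#' @export
tune_enm <- function(occ, stack, variables = names(stack$layers),
                     rms = seq(0.5, 4, by = 0.5),
                     fcs = c("L", "LQ", "H", "LQH", "LQHP", "LQHPT"),
                     background = NULL, n_background = 1000, n_knots = 50,
                     train_frac = 0.75, repeats = 10, seed = NULL,
                     tol = 1e-7, max_iter = 10000, progress = FALSE) {
  if (is.null(background)) {
    background <- sample_background(stack, n_background,
                                    seed = sub_seed(seed, "background"))
  }
  splits <- partition_occurrences(occ, train_frac, repeats,
                                  seed = sub_seed(seed, "partition"))
  pidx <- occ_cells(occ, stack)
  bidx <- occ_cells(background, stack)
  pres_raw <- extract_cells(stack, pidx$row, pidx$col, variables)
  bg_raw <- extract_cells(stack, bidx$row, bidx$col, variables)
  land_raw <- stack_values(stack, variables)$values

  grid <- expand.grid(fc = fcs, rm = rms, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (fc in fcs) {
    fspec <- build_features(stack, variables, fc, n_knots)
    Fp <- expand_features(fspec, pres_raw)
    Fb <- expand_features(fspec, bg_raw)
    Fl <- expand_features(fspec, land_raw)
    for (rm in rms) {
      fit <- maxent_fit_matrices(Fp, Fb, fspec$features$class, rm,
                                 tol = tol, max_iter = max_iter)
      kept <- names(fit$lambda)
      k <- sum(fit$lambda != 0)
      eta_occ <- as.numeric(Fp[, kept, drop = FALSE] %*% fit$lambda)
      eta_land <- as.numeric(Fl[, kept, drop = FALSE] %*% fit$lambda)
      aic <- aicc_from_eta(eta_occ, eta_land, k)
      auc_tr <- auc_te <- or10 <- numeric(length(splits))
      for (r in seq_along(splits)) {
        sp <- splits[[r]]
        pf <- maxent_fit_matrices(Fp[sp$train, , drop = FALSE], Fb,
                                  fspec$features$class, rm,
                                  tol = tol, max_iter = max_iter)
        keptp <- names(pf$lambda)
        sc_tr <- as.numeric(Fp[sp$train, keptp, drop = FALSE] %*% pf$lambda)
        sc_te <- as.numeric(Fp[sp$test, keptp, drop = FALSE] %*% pf$lambda)
        sc_bg <- as.numeric(Fb[, keptp, drop = FALSE] %*% pf$lambda)
        auc_tr[r] <- auc(sc_tr, sc_bg)
        auc_te[r] <- auc(sc_te, sc_bg)
        or10[r] <- omission10(sc_tr, sc_te)
      }
      i <- which(grid$fc == fc & grid$rm == rm)
      rows[[i]] <- data.frame(
        rm = rm, fc = fc,
        n_features = ncol(Fp), n_active = k,
        auc_train_avg = mean(auc_tr), auc_test_avg = mean(auc_te),
        auc_diff_avg = mean(auc_tr - auc_te),
        auc_diff_sd = stats::sd(auc_tr - auc_te),
        or10_avg = mean(or10), aicc = aic
      )
      if (progress) {
        message(sprintf("fc=%-6s rm=%3.1f  k=%3d  AICc=%s", fc, rm, k,
                        ifelse(is.na(aic), "NA", sprintf("%.2f", aic))))
      }
    }
  }
  results <- do.call(rbind, rows)
  results$delta_aicc <- results$aicc - min(results$aicc, na.rm = TRUE)
  sel <- select_candidate(results)
  results$selected <- seq_len(nrow(results)) == sel
  structure(list(
    results = results, selected = results[sel, ],
    seed = seed, train_frac = train_frac, repeats = repeats,
    n_background = nrow(background), n_knots = n_knots,
    variables = variables
  ), class = "enm_tuning")
}

#' @export
print.enm_tuning <- function(x, ...) {
  cat(sprintf("<enm_tuning> %d candidate(s); %d repeats of %d%%/%d%% splits\n",
              nrow(x$results), x$repeats, round(100 * x$train_frac),
              round(100 * (1 - x$train_frac))))
  s <- x$selected
  cat(sprintf("  selected: fc=%s, rm=%g (AICc %.2f, delta 0; test AUC %.3f, or10 %.3f)\n",
              s$fc, s$rm, s$aicc, s$auc_test_avg, s$or10_avg))
  invisible(x)
}

#' Write a tuning table to CSV
#'
#' @param tuning An [tune_enm()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tuning <- function(tuning, path) {
  utils::write.csv(tuning$results, path, row.names = FALSE)
  invisible(path)
}
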