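# Small generator/config presets so single tests stay fast.
small_gen <- function(...) {
  generator_settings(n_units_per_area = c(F5 = 6L, M1 = 8L), ...)
}

small_cfg <- function(trials = c(4L, 4L), ...) {
  task_config(trials_per_condition_range = trials, ...)
}

null_gen <- function(...) {
  generator_settings(tuned_frac_obj = 0, tuned_frac_mod = 0, ...)
}

# A minimal correct trial row with all paradigm events laid out.
toy_trial <- function(trial_id = 1L, object = "sphere", modality = "visual",
                      go = 3000, rt = 250, mt = 300, mem = 1200) {
  tibble::tibble(
    trial_id = trial_id,
    object = factor(object, levels = c("sphere", "ring", "bar", "cube",
                                       "blockring", "box")),
    modality = factor(modality, levels = c("visual", "tactile")),
    trial_start = go - mem - 700 - 500,
    cue_on = go - mem - 700,
    exploration_onset = NA_real_, exploration_lift = NA_real_,
    handrest_return = NA_real_,
    cue_off = go - mem,
    memory_start = go - mem,
    go = go,
    movement_onset = go + rt,
    object_lifted = go + rt + mt,
    hold_end = go + rt + mt + 700,
    reward = go + rt + mt + 750,
    outcome = "correct"
  )
}

# Greedy 1:1 event matching within a tolerance; returns precision/recall/F1.
match_events <- function(detected, truth, tol_ms = 0.5) {
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (t in truth) {
    d <- abs(detected - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_ms) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  precision <- if (length(detected)) tp / length(detected) else NA_real_
  recall <- if (length(truth)) tp / length(truth) else NA_real_
  c(precision = precision, recall = recall,
    f1 = 2 * tp / (length(detected) + length(truth)))
}

# Explicit balanced two-way ANOVA oracle from sums of squares (additive
# model, equal cell counts).
anova2_oracle <- function(y, a, b) {
  a <- as.factor(a); b <- as.factor(b)
  g <- mean(y)
  ssa <- sum(tapply(y, a, length) * (tapply(y, a, mean) - g)^2)
  ssb <- sum(tapply(y, b, length) * (tapply(y, b, mean) - g)^2)
  sst <- sum((y - g)^2)
  dfa <- nlevels(a) - 1
  dfb <- nlevels(b) - 1
  dfr <- length(y) - 1 - dfa - dfb
  ssr <- sst - ssa - ssb
  list(F_a = (ssa / dfa) / (ssr / dfr), F_b = (ssb / dfb) / (ssr / dfr),
       p_a = pf((ssa / dfa) / (ssr / dfr), dfa, dfr, lower.tail = FALSE),
       p_b = pf((ssb / dfb) / (ssr / dfr), dfb, dfr, lower.tail = FALSE))
}

# Regularized Mahalanobis nearest-class-mean oracle, independent of lda_fit.
mahal_oracle <- function(xtrain, labels, xtest, lambda_frac = 0.1) {
  labels <- droplevels(as.factor(labels))
  k <- nlevels(labels)
  mu <- rowsum(xtrain, labels) / as.vector(table(labels))
  resid <- xtrain - mu[as.integer(labels), , drop = FALSE]
  S <- crossprod(resid) / max(nrow(xtrain) - k, 1)
  S <- S + diag(max(lambda_frac * mean(diag(S)), 1e-8), ncol(xtrain))
  Sinv <- solve(S)
  apply(xtest, 1, function(x) {
    d2 <- apply(mu, 1, function(m) t(x - m) %*% Sinv %*% (x - m))
    levels(labels)[which.min(d2)]
  })
}

# Hand-assembled binned_counts container for direct ANOVA tests.
toy_binned <- function(counts, object, modality, centers = 0) {
  n_u <- dim(counts)[1]
  structure(list(
    counts = counts, centers_ms = centers, window_ms = 100, stride_ms = 100,
    align = "go",
    trials = tibble::tibble(trial_id = seq_along(object),
                            object = factor(object),
                            modality = factor(modality)),
    units = tibble::tibble(unit_id = sprintf("u%02d", seq_len(n_u)),
                           area = "F5")
  ), class = "binned_counts")
}
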