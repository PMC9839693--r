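# Metabolite concentration preprocessing (log + autoscale, with sum
# normalization for mouse stool) and PLS-DA separation diagnostics with
# leave-one-out and permutation validation.

#' Preprocess a concentration table for multivariate analysis
#'
#' `mouse_stool` rows are first divided by their row sum; all modes then take
#' natural logs and autoscale each metabolite to mean 0, sd 1. Zeros are
#' replaced before the log by half the smallest positive value of that
#' metabolite (minimum-replacement rule); metabolites with zero variance (or
#' no positive value) are dropped with a warning.
#'
#' @param c A `concentration_table`.
#' @param mode One of `"human_serum"`, `"human_stool"`, `"mouse_stool"`.
#' @return Numeric matrix (samples x retained metabolites) with column means
#'   0 and sds 1; dropped metabolites in `attr(, "dropped_metabolites")`.
#' @export
preprocess_concentrations <- function(c, mode = c("human_serum", "human_stool",
                                                  "mouse_stool")) {
  mode <- match.arg(mode)
  m <- c$values
  if (mode == "mouse_stool") {
    rs <- rowSums(m)
    if (any(rs == 0)) stop("preprocess_concentrations: zero-sum sample row")
    m <- m / rs
  }
  dropped <- character(0)
  keep <- rep(TRUE, ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    pos <- col[col > 0]
    if (!length(pos)) {
      keep[j] <- FALSE
      next
    }
    col[col == 0] <- min(pos) / 2
    m[, j] <- log(col)
  }
  sds <- apply(m, 2, stats::sd)
  keep <- keep & sds > 1e-12
  dropped <- colnames(m)[!keep]
  if (length(dropped)) {
    warning("preprocess_concentrations: dropping constant metabolite(s): ",
            paste(dropped, collapse = ", "))
  }
  m <- m[, keep, drop = FALSE]
  out <- scale(m)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "dropped_metabolites") <- dropped
  out
}

# NIPALS PLS1 on centered/scaled X and centered y; returns scores, loadings
# and the regression coefficient vector on the training scale.
pls1_fit <- function(X, y, ncomp) {
  m <- ncol(X)
  W <- P <- matrix(0, m, 0)
  Q <- numeric(0)
  Tm <- matrix(0, nrow(X), 0)
  Xd <- X
  yd <- y
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # nothing left to extract
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    p <- crossprod(Xd, t) / tt
    q <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, p)
    yd <- yd - q * as.vector(t)
    W <- cbind(W, w)
    P <- cbind(P, p)
    Q <- c(Q, q)
    Tm <- cbind(Tm, t)
  }
  B <- if (ncol(W)) W %*% solve(crossprod(P, W), Q) else matrix(0, m, 1)
  list(W = W, P = P, Q = Q, scores = Tm, coef = as.vector(B),
       ncomp_used = ncol(W))
}

center_scale <- function(X, center, scale_) sweep(sweep(X, 2, center), 2, scale_, "/")

# separation statistic: squared distance between class centroids in score
# space over the summed within-class score variance
separation_stat <- function(scores, y01) {
  s1 <- scores[y01 == 1, , drop = FALSE]
  s0 <- scores[y01 == 0, , drop = FALSE]
  between <- sum((colMeans(s1) - colMeans(s0))^2)
  within <- sum(apply(s1, 2, stats::var)) + sum(apply(s0, 2, stats::var))
  between / max(within, 1e-12)
}

# leave-one-out predicted scores: each fold refits the model, including the
# centering/scaling, without sample i
loo_predict <- function(X, y01, ncomp) {
  vapply(seq_len(nrow(X)), function(i) {
    tr <- plsda_engine(X[-i, , drop = FALSE], y01[-i], ncomp)
    xi <- (X[i, ] - tr$ctr) / tr$scl
    sum(xi * tr$fit$coef) + mean(y01[-i])
  }, 0)
}

loo_accuracy <- function(X, y01, ncomp) {
  mean(as.numeric(loo_predict(X, y01, ncomp) > 0.5) == y01)
}

plsda_engine <- function(X, y01, ncomp) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- center_scale(X, ctr, scl)
  yc <- y01 - mean(y01)
  fit <- pls1_fit(Xs, yc, ncomp)
  yhat <- as.vector(Xs %*% fit$coef) + mean(y01)
  list(fit = fit, yhat = yhat, ctr = ctr, scl = scl, Xs = Xs)
}

#' PLS-DA fit with leave-one-out and permutation validation
#'
#' Fits a two-class partial least-squares discriminant model by iterative
#' latent-variable extraction with deflation (NIPALS, class coded 0/1) and
#' reports the standard metabolomics validation battery: R2 (1 - RSS/TSS on
#' the training fit), Q2 (1 - PRESS/TSS under leave-one-out), leave-one-out
#' prediction accuracy, classification error rate (CER = 1 - accuracy),
#' AUROC of the leave-one-out predicted scores, and label-permutation
#' p-values (+1 convention) for the class-separation distance and training
#' accuracy.
#'
#' @param X Numeric matrix, samples x variables (autoscaled internally, so
#'   results are invariant to per-variable scaling).
#' @param y Binary labels (factor or vector with exactly 2 levels), both
#'   classes with >= 3 samples.
#' @param n_comp Number of latent components (default 2).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @return Object of class `plsda_report` with fields `n_components`, `R2`,
#'   `Q2`, `accuracy`, `CER`, `AUROC`, `permutation_p_separation`,
#'   `permutation_p_accuracy`, `scores`, `loo_scores`, `n_perm`, `seed`.
#' @export
plsda_validate <- function(X, y, n_comp = 2, n_perm = 1000, seed = 1L) {
  y <- factor(y)
  if (nlevels(y) != 2) stop("plsda_validate: need exactly 2 classes")
  if (any(table(y) < 3)) stop("plsda_validate: both classes need >= 3 samples")
  X <- as.matrix(X)
  n <- nrow(X)
  y01 <- as.numeric(y == levels(y)[2])
  full <- plsda_engine(X, y01, n_comp)
  tss <- sum((y01 - mean(y01))^2)
  R2 <- 1 - sum((y01 - full$yhat)^2) / tss
  loo <- loo_predict(X, y01, n_comp)
  Q2 <- 1 - sum((y01 - loo)^2) / tss
  pred_class <- as.numeric(loo > 0.5)
  accuracy <- mean(pred_class == y01)
  auroc <- auc_rank(loo, y01)
  # permutation nulls: separation distance from the full fit, accuracy from
  # the leave-one-out predictions (training accuracy saturates for wide X,
  # which would make the accuracy null uninformative)
  sep_obs <- separation_stat(full$fit$scores, y01)
  withr::local_seed(seed)
  sep_ge <- acc_ge <- 0L
  for (b in seq_len(n_perm)) {
    yp <- y01[sample.int(n)]
    pf <- plsda_engine(X, yp, n_comp)
    if (separation_stat(pf$fit$scores, yp) >= sep_obs - 1e-12) sep_ge <- sep_ge + 1L
    if (loo_accuracy(X, yp, n_comp) >= accuracy - 1e-12) acc_ge <- acc_ge + 1L
  }
  structure(list(n_components = full$fit$ncomp_used,
                 R2 = R2, Q2 = Q2,
                 accuracy = accuracy, CER = 1 - accuracy, AUROC = auroc,
                 permutation_p_separation = (1 + sep_ge) / (1 + n_perm),
                 permutation_p_accuracy = (1 + acc_ge) / (1 + n_perm),
                 scores = full$fit$scores,
                 loo_scores = loo,
                 classes = levels(y),
                 n_perm = as.integer(n_perm), seed = seed),
            class = "plsda_report")
}

# Mann-Whitney rank formula for the area under the ROC curve
auc_rank <- function(score, y01) {
  r <- rank(score)
  n1 <- sum(y01 == 1)
  n0 <- sum(y01 == 0)
  (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.plsda_report <- function(x, ...) {
  cat(sprintf(
    "PLS-DA (%d components): R2 = %.3f, Q2 = %.3f, accuracy = %.3f, CER = %.3f, AUROC = %.3f\n  permutation p: separation %.4g, accuracy %.4g (%d permutations)\n",
    x$n_components, x$R2, x$Q2, x$accuracy, x$CER, x$AUROC,
    x$permutation_p_separation, x$permutation_p_accuracy, x$n_perm))
  invisible(x)
}
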