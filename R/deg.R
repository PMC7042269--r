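#' Fit per-gene linear models
#'
#' Fits, by least squares, the model
#' `expression ~ condition + covariates` to every gene of a study and returns
#' the condition coefficient (log2 units), the residual variance and its
#' degrees of freedom. All genes share one design matrix, so the fit is a
#' single QR decomposition applied across the expression matrix.
#'
#' @param study An [expression_study()].
#' @return A data.frame with one row per gene: `gene`, `beta` (condition
#'   coefficient), `s2` (residual variance), `df` (residual degrees of
#'   freedom), `se_unscaled` (standard error of `beta` per unit residual sd)
#'   and `zero_variance` flag. Zero-variance genes get `beta = 0`, `s2 = 0`.
#' @export
fit_gene_models <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  X <- design_matrix(study)
  n <- nrow(X)
  qrX <- qr(X)
  r <- qrX$rank
  if (r < ncol(X)) {
    keep <- qrX$pivot[seq_len(r)]
    drop <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(drop, collapse = ", "))
  }
  if (n <= ncol(X))
    stop("need more samples than model coefficients")
  Y <- t(study$values)                       # samples x genes
  coefs <- qr.coef(qrX, Y)                   # p x genes
  res <- qr.resid(qrX, Y)
  dfres <- n - r
  s2 <- colSums(res^2) / dfres
  # (X'X)^-1 diagonal for the condition column -> unscaled se of beta
  XtXinv <- chol2inv(qr.R(qrX))
  cond_ix <- match("condition", colnames(X))
  se_unscaled <- sqrt(XtXinv[cond_ix, cond_ix])
  beta <- coefs[cond_ix, ]
  zv <- study$zero_variance
  beta[zv] <- 0
  s2[zv] <- 0
  data.frame(gene = rownames(study$values), beta = as.numeric(beta),
             s2 = as.numeric(s2), df = dfres, se_unscaled = se_unscaled,
             zero_variance = zv, row.names = NULL,
             stringsAsFactors = FALSE)
}

# Internal: design matrix with intercept, condition, covariates.
design_matrix <- function(study) {
  d <- data.frame(condition = study$condition)
  if (!is.null(study$covariates)) d <- cbind(d, study$covariates)
  X <- stats::model.matrix(~ ., data = d)
  colnames(X)[colnames(X) == "(Intercept)"] <- "intercept"
  X
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks per-gene residual variances toward a common prior by assuming
#' `s2_g ~ s0^2 * F(d_g, d0)` (a scaled-F / inverse-chi-square prior on the
#' true variances) and estimating the prior degrees of freedom `d0` and prior
#' variance `s0^2` by matching the first two moments of `log(s2_g)`. The
#' moderated variance is the standard weighted combination
#' `(d0*s0^2 + d*s2_g) / (d0 + d)`.
#'
#' @param s2 Vector of residual variances.
#' @param df Residual degrees of freedom (scalar or vector).
#' @param d0,s02 Optional fixed prior parameters; estimated when `NULL`.
#'   `d0 = 0` disables shrinkage, `d0 = Inf` forces `s2_tilde = s02`.
#' @return List with `s2_tilde` (moderated variances), `d0`, `s02`, and
#'   `df_total = d0 + df` (degrees of freedom of the moderated t). Zero or
#'   non-finite variances are excluded from the moment matching; their
#'   moderated value is the prior `s02`.
#' @export
moderate_variances <- function(s2, df, d0 = NULL, s02 = NULL) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0
  if (is.null(d0) || is.null(s02)) {
    if (sum(ok) < 2L) stop("need at least 2 genes with positive variance")
    z <- log(s2[ok])
    e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
    emean <- mean(e)
    evar <- sum((e - emean)^2) / (sum(ok) - 1L) - mean(trigamma(df[ok] / 2))
    if (is.null(d0)) {
      if (evar <= 0) {
        d0 <- Inf
      } else {
        d0 <- 2 * trigamma_inverse(evar)
      }
    }
    if (is.null(s02)) {
      s02 <- if (is.finite(d0))
        exp(emean + digamma(d0 / 2) - log(d0 / 2))
      else exp(emean)
    }
  }
  s2_tilde <- if (is.infinite(d0)) rep_len(s02, length(s2)) else
    (d0 * s02 + df * s2) / (d0 + df)
  s2_tilde[!ok] <- if (is.infinite(d0)) s02 else
    (d0 * s02) / (d0 + df[!ok])
  if (d0 == 0) s2_tilde[!ok] <- s2[!ok]
  list(s2_tilde = s2_tilde, d0 = d0, s02 = s02, df_total = d0 + df)
}

# Internal: solve trigamma(y) = x by Newton iteration on 1/trigamma,
# which is nearly linear in x.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_(j >= i) p_(j) * m / j`, clipped to 1.
#'
#' @param p Vector of p-values in `[0, 1]`; `NA`/`NaN` is an error.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) stop("p-values must not contain NA/NaN")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential expression table
#'
#' Runs the per-gene linear models, moderates the variances, computes
#' moderated t statistics, two-sided p-values, BH q-values and fold-changes
#' `FC = 2^beta`, and flags genes at the FDR threshold.
#'
#' Zero-variance genes are retained with `p = 1` and excluded from the prior
#' moment matching.
#'
#' @param study An [expression_study()].
#' @param fdr_threshold FDR level for the DEG flag (default 0.01).
#' @param d0,s02 Optional fixed moderation prior (see [moderate_variances()]).
#' @return A `deg_table` data.frame: `gene`, `beta`, `fc`, `t`, `p`, `q`,
#'   `deg` (logical), `direction` ("up"/"down"/"none").
#' @export
deg_table <- function(study, fdr_threshold = 0.01, d0 = NULL, s02 = NULL) {
  fit <- fit_gene_models(study)
  mod <- moderate_variances(fit$s2, fit$df, d0 = d0, s02 = s02)
  tstat <- fit$beta / (fit$se_unscaled * sqrt(mod$s2_tilde))
  p <- 2 * stats::pt(-abs(tstat), df = mod$df_total)
  tstat[fit$zero_variance] <- 0
  p[fit$zero_variance] <- 1
  q <- bh_adjust(p)
  deg <- q <= fdr_threshold
  out <- data.frame(
    gene = fit$gene, beta = fit$beta, fc = 2^fit$beta, t = tstat,
    p = p, q = q, deg = deg,
    direction = ifelse(!deg, "none", ifelse(fit$beta > 0, "up", "down")),
    stringsAsFactors = FALSE
  )
  attr(out, "moderation") <- list(d0 = mod$d0, s02 = mod$s02)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Call differentially expressed genes
#'
#' @param degs A [deg_table()] data.frame.
#' @param fdr_threshold FDR level (defaults to the flag already stored).
#' @return List with `up`, `down` (gene vectors), and `proportions` (fraction
#'   of DEGs up/down).
#' @export
call_degs <- function(degs, fdr_threshold = NULL) {
  q <- degs$q
  sel <- if (is.null(fdr_threshold)) degs$deg else q <= fdr_threshold
  up <- degs$gene[sel & degs$beta > 0]
  down <- degs$gene[sel & degs$beta < 0]
  n <- length(up) + length(down)
  list(up = up, down = down,
       proportions = c(up = if (n) length(up) / n else NA_real_,
                       down = if (n) length(down) / n else NA_real_))
}
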