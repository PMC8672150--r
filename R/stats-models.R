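#' Binomial GLMM for one phenotype's differential abundance
#'
#' Fits `logit(mu) = b0 + b1 * responder` with a subject-level Gaussian
#' random intercept to per-sample counts `c` out of totals `n`, and returns
#' the Wald test of the responder coefficient. Non-convergent or degenerate
#' fits are flagged and carry `NA` p-values; when `fallback = TRUE` a
#' beta-binomial fixed-effect model (glmmTMB) is attempted first and flagged
#' distinctly.
#'
#' @param counts,totals integer vectors per sample.
#' @param responder 0/1 (or logical) indicator per sample.
#' @param subject grouping factor for the random effect (default: one level
#'   per sample, i.e. an observation-level random effect).
#' @param fallback try a beta-binomial fixed-effect model when the GLMM
#'   fails.
#' @return list: `beta0`, `beta1`, `re_sd`, `se`, `p_value`, `method`,
#'   `converged`.
#' @export
fit_binomial_glmm <- function(counts, totals, responder,
                              subject = seq_along(counts), fallback = TRUE) {
  stopifnot(length(counts) == length(totals),
            length(responder) == length(counts),
            all(counts >= 0), all(counts <= totals))
  df <- data.frame(c = counts, n = totals, r = as.numeric(responder),
                   s = factor(subject))
  # a Wald se below the no-overdispersion binomial information bound marks a
  # degenerate fit (the mixed/beta-binomial model can only add variance)
  se_floor <- 0.5 * sqrt(1 / (sum(counts[df$r == 1]) + 0.5) +
                           1 / (sum(counts[df$r == 0]) + 0.5))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::glmer(cbind(c, n - c) ~ r + (1 | s), data = df, family = binomial())
    )), error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- lme4::fixef(fit)
    vc <- suppressWarnings(as.matrix(vcov(fit)))
    se <- suppressWarnings(sqrt(vc["r", "r"]))
    msgs <- unlist(fit@optinfo$conv$lme4$messages)
    conv_ok <- is.null(msgs) || all(grepl("boundary", msgs))  # singular RE is fine
    conv <- conv_ok && is.finite(se) && se > se_floor
    if (conv) {
      z <- cf[["r"]] / se
      return(list(beta0 = cf[["(Intercept)"]], beta1 = cf[["r"]],
                  re_sd = sqrt(unlist(lme4::VarCorr(fit))[[1]]),
                  se = se, p_value = 2 * pnorm(-abs(z)),
                  method = "binomial_glmm", converged = TRUE))
    }
  }
  if (fallback && requireNamespace("glmmTMB", quietly = TRUE)) {
    bb <- tryCatch(
      suppressWarnings(glmmTMB::glmmTMB(cbind(c, n - c) ~ r, data = df,
                                        family = glmmTMB::betabinomial())),
      error = function(e) NULL)
    if (!is.null(bb) && isTRUE(bb$sdr$pdHess)) {
      sm <- summary(bb)$coefficients$cond
      if ("r" %in% rownames(sm) && is.finite(sm["r", "Std. Error"]) &&
          sm["r", "Std. Error"] > se_floor) {
        return(list(beta0 = sm["(Intercept)", "Estimate"],
                    beta1 = sm["r", "Estimate"], re_sd = NA_real_,
                    se = sm["r", "Std. Error"],
                    p_value = sm["r", "Pr(>|z|)"],
                    method = "betabinomial_fallback", converged = TRUE))
      }
    }
  }
  list(beta0 = NA_real_, beta1 = NA_real_, re_sd = NA_real_, se = NA_real_,
       p_value = NA_real_, method = "failed", converged = FALSE)
}

#' Differential abundance across all phenotypes of a count matrix
#'
#' Per-phenotype binomial GLMM ([fit_binomial_glmm]) with multiplicity
#' adjustment across phenotypes (Bonferroni by default).
#'
#' @param counts a [build_count_matrix] result (samples x phenotypes).
#' @param responder per-sample 0/1 indicator.
#' @param subject per-sample grouping factor.
#' @param totals per-sample totals (default: the count matrix attribute).
#' @param adjust `"bonferroni"` or `"BH"`.
#' @return data.frame: phenotype, estimate, se, direction, p, p_adj, method.
#' @export
differential_abundance <- function(counts, responder, subject = NULL,
                                   totals = attr(counts, "totals"),
                                   adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(subject)) subject <- rownames(counts) %||% seq_len(nrow(counts))
  res <- lapply(colnames(counts), function(ph) {
    f <- fit_binomial_glmm(counts[, ph], totals, responder, subject)
    data.frame(phenotype = ph, estimate = f$beta1, se = f$se,
               direction = sign(f$beta1), p = f$p_value, method = f$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- adjust_pvalues(out$p, method = adjust)
  out
}

#' Multiplicity adjustment
#'
#' @param pvalues numeric vector in `[0, 1]` (NAs preserved).
#' @param method `"bonferroni"` or `"BH"`.
#' @return adjusted p-values, capped at 1, never below the raw values.
#' @export
adjust_pvalues <- function(pvalues, method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  p.adjust(pvalues, method = method)
}

#' Joint phenotypic and functional differential abundance (PFDA)
#'
#' Fits one binomial mixed model jointly to all `k` phenotypes matching a
#' partial annotation: responder main effect, cluster main effects, cluster
#' x responder interactions, and an observation-level Gaussian random
#' effect. Differential abundance is tested through the one-sided linear
#' combination `bR + (1/k) * sum_j b_{R x cluster_j}` (computed so the
#' contrast is invariant to the reference-level parameterization), with a
#' normal-approximation p-value and one-sided confidence bound.
#'
#' @param counts samples x phenotypes count matrix (the matching subset).
#' @param totals per-sample totals.
#' @param responder per-sample 0/1 indicator.
#' @param conf_level one-sided confidence level (default 0.95).
#' @return list: `contrast`, `se`, `p_value` (one-sided, H1: contrast > 0),
#'   `lower` (one-sided bound), `k`, `converged`.
#' @export
pfda_test <- function(counts, totals, responder, conf_level = 0.95) {
  k <- ncol(counts)
  if (is.null(k) || k < 1) stop("no phenotypes match target")
  n <- nrow(counts)
  long <- data.frame(
    c = as.vector(counts),
    n = rep(totals, times = k),
    r = rep(as.numeric(responder), times = k),
    cluster = factor(rep(seq_len(k), each = n)),
    obs = factor(seq_len(n * k))
  )
  if (k == 1) {
    f <- fit_binomial_glmm(long$c, long$n, long$r, subject = long$obs)
    est <- f$beta1; se <- f$se
    return(list(contrast = est, se = se,
                p_value = if (is.na(se)) NA_real_ else pnorm(est / se, lower.tail = FALSE),
                lower = est - stats::qnorm(conf_level) * se, k = 1L,
                converged = f$converged))
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::glmer(cbind(c, n - c) ~ r + cluster + r:cluster + (1 | obs),
                  data = long, family = binomial())
    )), error = function(e) NULL)
  if (is.null(fit))
    return(list(contrast = NA_real_, se = NA_real_, p_value = NA_real_,
                lower = NA_real_, k = k, converged = FALSE))
  cf <- lme4::fixef(fit)
  vc <- as.matrix(vcov(fit))
  # contrast = average over clusters of the responder effect:
  # bR + (1/k) * sum over non-reference interactions
  w <- setNames(numeric(length(cf)), names(cf))
  w["r"] <- 1
  ints <- grep("^r:cluster", names(cf), value = TRUE)
  w[ints] <- 1 / k
  est <- sum(w * cf)
  se <- sqrt(drop(t(w) %*% vc %*% w))
  list(contrast = est, se = se,
       p_value = pnorm(est / se, lower.tail = FALSE),
       lower = est - stats::qnorm(conf_level) * se, k = k,
       converged = length(fit@optinfo$conv$lme4) == 0)
}
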