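# Thin R front over the compiled IRLS fitter. All likelihood-based
# evaluation (Nagelkerke R^2, OR per SD, LRT scans) goes through here so the
# separation/non-convergence policy is in one place: 25 IRLS iterations,
# then a ridge refit (penalty 1e-6) flagged as "capped", whose penalized
# log-likelihood is what gets reported.
fit_logistic <- function(x, y, max_iter = 25L, tol = 1e-8) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  res <- cpp_logistic_fit(x, y, max_iter, tol)
  res$coef <- drop(res$coef)
  res$se <- drop(res$se)
  names(res$coef) <- names(res$se) <- colnames(x)
  if (res$capped)
    warning("logistic fit capped: ridge fallback used (possible separation)",
            call. = FALSE)
  res
}
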