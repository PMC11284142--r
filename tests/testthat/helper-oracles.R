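# Independent oracles used to cross-check the package's geometry and ICC.

# Geometric (orthogonal-distance) least-squares circle via general-purpose
# optimisation over the center; radius is the mean radial distance at the
# optimum. Independent of the closed-form algebraic fit in the package.
oracle_circle_center <- function(points) {
  points <- as.matrix(points)
  obj <- function(c0) {
    d <- sqrt((points[, 1] - c0[1])^2 + (points[, 2] - c0[2])^2)
    sum((d - mean(d))^2)
  }
  start <- colMeans(points)
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  fit$par
}

# First principal direction via prcomp (SVD path), as angle in (-90, 90].
oracle_line_angle <- function(points) {
  points <- as.matrix(points)
  v <- prcomp(points)$rotation[, 1]
  unname(torsionCT::fold_angle(atan2(v[2], v[1]) * 180 / pi))
}

# Two-way ANOVA mean squares via stats::aov on the long layout.
oracle_anova_ms <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  long <- data.frame(
    y = as.vector(mat),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(aov(y ~ subject + rater, data = long))[[1]]
  list(msr = tab["subject", "Mean Sq"],
       msc = tab["rater", "Mean Sq"],
       mse = tab["Residuals", "Mean Sq"])
}

# ICC point estimates from oracle mean squares (textbook definitions).
oracle_icc <- function(mat, model) {
  ms <- oracle_anova_ms(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (model == "two-way-mixed-consistency") {
    (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
  } else {
    (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
  }
}

# Random true angles within a comfortably identifiable range.
random_truth <- function() {
  list(proximal = runif(1, -40, 40),
       distal_talar = runif(1, -40, 40),
       fibular_offset = runif(1, -12, 12))
}

measured_four <- function(tib) {
  c(ptta = measure_ptta(tib$proximal)$value,
    pmtpa = measure_pmtpa(tib$proximal)$value,
    ima = measure_ima(tib$ankle)$value,
    ta = measure_ta(tib$ankle)$value)
}
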