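#' Options for maximum-likelihood model fitting
#'
#' @param kappa_bounds,omega_bounds,bl_bounds Lower/upper box bounds for the
#'   transition/transversion ratio, the omega ratios, and the branch lengths
#'   (expected substitutions per codon). The omega lower bound of `1e-4` keeps
#'   boundary estimates for fully conserved clades representable.
#' @param n_starts Number of optimisation starts: the deterministic heuristic
#'   start plus `n_starts - 1` seeded log-scale jitters of it.
#' @param seed Seed for the multistart jitter stream.
#' @param maxit,factr,pgtol Passed to [stats::optim()]'s `L-BFGS-B` control.
#' @param init_kappa,init_omega Starting values for the heuristic start.
#' @return List of class `fit_opts`.
#' @export
fit_opts <- function(kappa_bounds = c(0.05, 50),
                     omega_bounds = c(1e-4, 50),
                     bl_bounds = c(1e-8, 20),
                     n_starts = 2L,
                     seed = 1L,
                     maxit = 500L,
                     factr = 1e7,
                     pgtol = 1e-8,
                     init_kappa = 2,
                     init_omega = 0.4) {
  structure(as.list(environment()), class = "fit_opts")
}

# Heuristic starting branch lengths: mean pairwise codon p-distance spread
# over the mean tip-to-tip path length in edges (star-decomposition flavour).
.init_branch_lengths <- function(aln, tree) {
  states <- .codon_states(aln)
  n <- nrow(states)
  if (n < 2L) return(rep(0.01, nrow(tree$phylo$edge)))
  pd <- 0
  np <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      pd <- pd + mean(states[i, ] != states[j, ])
      np <- np + 1
    }
  }
  pbar <- pd / np
  phy <- tree$phylo
  unit <- phy
  unit$edge.length <- rep(1, nrow(phy$edge))
  mean_path <- mean(ape::cophenetic.phylo(unit)[upper.tri(diag(n))])
  bl <- pbar / max(mean_path, 1)
  rep(min(max(bl, 0.005), 2), nrow(phy$edge))
}

# theta layout: log(kappa), log(omega_1..K), log(bl_1..E).
.fit_codon_model <- function(aln, tree, n_omega, opts, init_fit = NULL) {
  ctx <- .loglik_context(aln, tree)
  pi <- f3x4_frequencies(aln)
  pi <- as.numeric(pi)
  ne <- ctx$n_edge
  if (n_omega > 1L && ctx$n_part < 2L) {
    stop("tree lacks a foreground partition (all branches background)")
  }
  # Partition id -> omega slot: M0 maps every partition to the single omega.
  part_to_omega <- if (n_omega == 1L) rep(1L, ctx$n_part) else seq_len(ctx$n_part)

  lower <- log(c(opts$kappa_bounds[1], rep(opts$omega_bounds[1], n_omega),
                 rep(opts$bl_bounds[1], ne)))
  upper <- log(c(opts$kappa_bounds[2], rep(opts$omega_bounds[2], n_omega),
                 rep(opts$bl_bounds[2], ne)))
  n_eval <- 0L
  negll <- function(theta) {
    n_eval <<- n_eval + 1L
    kappa <- exp(theta[1])
    omega <- exp(theta[2:(1 + n_omega)])
    bl <- exp(theta[-(1:(1 + n_omega))])
    v <- tryCatch(
      .loglik_eval(ctx, kappa, omega[part_to_omega], pi, bl),
      error = function(e) -Inf
    )
    if (!is.finite(v)) return(1e10)
    -v
  }

  starts <- list()
  bl0 <- .init_branch_lengths(aln, tree)
  starts[[1]] <- log(c(opts$init_kappa, rep(opts$init_omega, n_omega), bl0))
  if (!is.null(init_fit)) {
    om <- init_fit$omega
    om <- if (length(om) >= n_omega) om[seq_len(n_omega)] else
      rep(om[length(om)], n_omega)
    starts[[1]] <- log(c(init_fit$kappa, om, init_fit$branch_lengths))
  }
  if (opts$n_starts > 1L) {
    jit <- with_seed(opts$seed, lapply(seq_len(opts$n_starts - 1L), function(i) {
      starts[[1]] + stats::rnorm(length(starts[[1]]), sd = 0.5)
    }))
    starts <- c(starts, jit)
  }
  starts <- lapply(starts, function(s) pmin(pmax(s, lower), upper))

  best <- NULL
  conv <- FALSE
  for (s in starts) {
    res <- tryCatch(
      optim(s, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = opts$maxit, factr = opts$factr,
                           pgtol = opts$pgtol)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) {
      best <- res
      conv <- res$convergence == 0L
    }
  }
  if (is.null(best)) stop("optimiser failed on every start")
  theta <- best$par
  kappa <- exp(theta[1])
  omega <- exp(theta[2:(1 + n_omega)])
  bl <- exp(theta[-(1:(1 + n_omega))])
  structure(
    list(
      lnL = -best$value,
      kappa = kappa,
      omega = setNames(omega, paste0("omega_", seq_len(n_omega) - 1L)),
      branch_lengths = bl,
      pi = pi,
      tree = tree,
      se = NULL,
      converged = conv,
      n_iterations = best$counts[["function"]],
      n_evaluations = n_eval,
      model_tag = if (n_omega == 1L) "M0" else "CLADES",
      opts = opts,
      part_to_omega = part_to_omega
    ),
    class = "codon_fit"
  )
}

#' Fit the one-ratio (M0) codon model
#'
#' Jointly maximises the log-likelihood over kappa, a single omega shared by
#' all branches, and all branch lengths, by bounded quasi-Newton optimisation
#' on log-transformed parameters.
#'
#' @param aln Filtered codon-mode [codon_alignment()].
#' @param tree A [clade_tree()] (partition labels are ignored by M0).
#' @param opts A [fit_opts()] list.
#' @return Object of class `codon_fit` with elements `lnL`, `kappa`, `omega`,
#'   `branch_lengths`, `converged`, `model_tag`, and later `se` (see
#'   [standard_errors()]).
#' @export
fit_m0 <- function(aln, tree, opts = fit_opts()) {
  .fit_codon_model(aln, tree, n_omega = 1L, opts = opts)
}

#' Fit the two-clades codon model
#'
#' Maximises the log-likelihood with a background omega (partition 0) and a
#' separate foreground omega (partition 1), plus kappa and all branch lengths.
#' Because M0 is nested in this model, `fit_clades(...)$lnL` is at least
#' `fit_m0(...)$lnL` up to optimiser tolerance; passing the M0 fit as `init`
#' starts the search at the M0 optimum and enforces that inequality
#' numerically.
#'
#' @inheritParams fit_m0
#' @param tree A [clade_tree()] with exactly two partitions.
#' @param init Optional `codon_fit` (typically the M0 fit on the same data)
#'   used as the first optimisation start.
#' @return A `codon_fit` with `omega` of length 2 (`omega_0` background,
#'   `omega_1` foreground).
#' @export
fit_clades <- function(aln, tree, opts = fit_opts(), init = NULL) {
  if (tree$n_partitions != 2L) {
    stop("the clades model needs exactly 2 partitions; tree has ",
         tree$n_partitions)
  }
  .fit_codon_model(aln, tree, n_omega = 2L, opts = opts, init_fit = init)
}

#' @export
print.codon_fit <- function(x, ...) {
  cat(sprintf("<codon_fit:%s> lnL = %.4f, kappa = %.3f\n",
              x$model_tag, x$lnL, x$kappa))
  om <- sprintf("%s = %.4g", names(x$omega), x$omega)
  if (!is.null(x$se)) {
    se <- x$se[names(x$omega)]
    om <- paste0(om, ifelse(is.na(se), " (SE undefined)",
                            sprintf(" (SE %.3g)", se)))
  }
  cat(" ", paste(om, collapse = "; "), "\n")
  cat(sprintf("  %d branch lengths, converged: %s\n",
              length(x$branch_lengths), x$converged))
  invisible(x)
}

# Central finite-difference Hessian of fn at x with per-coordinate steps h.
.fd_hessian <- function(fn, x, h) {
  n <- length(x)
  H <- matrix(NA_real_, n, n)
  f0 <- fn(x)
  for (i in seq_len(n)) {
    ei <- replace(numeric(n), i, h[i])
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h[i]^2
    if (i < n) {
      for (j in seq(i + 1L, n)) {
        ej <- replace(numeric(n), j, h[j])
        H[i, j] <- H[j, i] <-
          (fn(x + ei + ej) - fn(x + ei - ej) -
             fn(x - ei + ej) + fn(x - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Standard errors of the model parameters
#'
#' Curvature-based (observed-information) standard errors for kappa and the
#' omega ratios: the central finite-difference Hessian of the log-likelihood
#' at the MLE is inverted and the square roots of its diagonal reported. By
#' default branch lengths are held at their MLEs; with
#' `include_branch_lengths = TRUE` they enter the Hessian too. An SE is
#' reported as `NA` (undefined) when the estimate sits at a box bound -- e.g.
#' an omega driven to the lower bound by a fully conserved clade -- or when
#' the information matrix is not positive definite there.
#'
#' @param fit A converged `codon_fit`.
#' @param aln,tree The data the fit was computed on.
#' @param include_branch_lengths Include branch lengths in the Hessian block?
#' @return The fit, with `se` filled in (named: `kappa`, `omega_0`, ...).
#' @export
standard_errors <- function(fit, aln, tree, include_branch_lengths = FALSE) {
  stopifnot(inherits(fit, "codon_fit"))
  ctx <- .loglik_context(aln, tree)
  pi <- fit$pi
  p2o <- fit$part_to_omega
  nom <- length(fit$omega)
  est <- c(kappa = unname(fit$kappa), fit$omega)
  if (include_branch_lengths) {
    est <- c(est, setNames(fit$branch_lengths,
                           paste0("bl_", seq_along(fit$branch_lengths))))
  }
  nbl <- length(fit$branch_lengths)
  fn <- function(x) {
    kappa <- x[1]
    omega <- x[2:(1 + nom)]
    bl <- if (include_branch_lengths) x[-(1:(1 + nom))] else fit$branch_lengths
    if (kappa <= 0 || any(omega < 0) || any(bl < 0)) return(-Inf)
    .loglik_eval(ctx, kappa, omega[p2o], pi, bl)
  }
  h <- pmax(1e-5, 1e-3 * abs(est))
  H <- .fd_hessian(fn, est, h)
  se <- rep(NA_real_, length(est))
  ok_info <- all(is.finite(H))
  if (!ok_info) stop("non-finite Hessian entries")
  vcv <- tryCatch(solve(-H), error = function(e) NULL)
  if (!is.null(vcv)) {
    d <- diag(vcv)
    ok <- which(is.finite(d) & d > 0)
    se[ok] <- sqrt(d[ok])
  }
  # Estimates at (or hugging) a bound have no interior curvature to report.
  bounds <- rbind(
    kappa = fit$opts$kappa_bounds,
    matrix(rep(fit$opts$omega_bounds, each = nom), nom, 2,
           dimnames = list(names(fit$omega), NULL))
  )
  if (include_branch_lengths) {
    bounds <- rbind(bounds, matrix(rep(fit$opts$bl_bounds, each = nbl),
                                   nbl, 2))
  }
  at_bound <- est <= bounds[, 1] * (1 + 1e-2) + 1e-12 |
    est >= bounds[, 2] * (1 - 1e-2)
  se[at_bound] <- NA_real_
  fit$se <- setNames(se, names(est))
  fit
}

#' Likelihood-ratio test of nested codon models
#'
#' Computes the statistic `Delta = 2 (lnL_alt - lnL_null)` for two nested
#' fits and compares it to the upper tail of a chi-squared distribution. For
#' the one-ratio (M0) model nested in the two-clades model the difference is
#' a single omega parameter, so `df = 1`. Small negative `Delta` from
#' optimiser tolerance is clamped to zero.
#'
#' @param null_fit,alt_fit `codon_fit` objects for the nested (M0) and the
#'   richer (clades) model on the same data.
#' @param df Degrees of freedom (difference in free parameters), >= 1.
#' @return Object of class `lrt_result`: list with `delta`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(null_fit, alt_fit, df = 1L) {
  stopifnot(inherits(null_fit, "codon_fit"), inherits(alt_fit, "codon_fit"))
  if (df < 1L) stop("df must be >= 1")
  nesting <- c(M0 = 1L, CLADES = 2L)
  if (is.na(nesting[null_fit$model_tag]) || is.na(nesting[alt_fit$model_tag]) ||
      nesting[null_fit$model_tag] >= nesting[alt_fit$model_tag]) {
    stop("models are not nested in the required direction (null: ",
         null_fit$model_tag, ", alt: ", alt_fit$model_tag, ")")
  }
  delta <- 2 * (alt_fit$lnL - null_fit$lnL)
  if (delta < -1e-6) {
    warning("alternative lnL below null by ", format(-delta / 2),
            "; refit with better starts (delta clamped to 0)")
  }
  delta <- max(delta, 0)
  structure(
    list(delta = delta, df = as.integer(df),
         p = pchisq(delta, df = df, lower.tail = FALSE)),
    class = "lrt_result"
  )
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: Delta = %.4f, df = %d, p = %.4g\n", x$delta, x$df, x$p))
  invisible(x)
}
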