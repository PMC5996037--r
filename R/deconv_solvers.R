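#' Solver specification for deconvolution
#'
#' @param method One of \code{"llsr"}, \code{"qp"}, \code{"ridge"},
#'   \code{"lasso"}, \code{"elastic_net"}, \code{"nu_svr"}.
#' @param seed Integer seed driving cross-validation fold assignment.
#' @param nu_grid Candidate nu values for nu-SVR.
#' @param cost SVR cost parameter C, default 1.
#' @param lambda Optional fixed penalty for the penalized methods; when NULL
#'   (default) lambda is chosen by 5-fold cross-validation over genes.
#' @param lambda_grid Penalty grid searched by cross-validation.
#' @param nfolds Number of CV folds, default 5.
#' @return A list of class \code{solver_spec}.
#' @export
solver_spec <- function(method = c("llsr", "qp", "ridge", "lasso",
                                   "elastic_net", "nu_svr"),
                        seed = 1L,
                        nu_grid = c(0.25, 0.5, 0.75),
                        cost = 1,
                        lambda = NULL,
                        lambda_grid = 10^seq(2, -4, length.out = 100),
                        nfolds = 5L) {
  method <- match.arg(method)
  structure(list(method = method, seed = as.integer(seed), nu_grid = nu_grid,
                 cost = cost, lambda = lambda,
                 lambda_grid = sort(lambda_grid, decreasing = TRUE),
                 nfolds = as.integer(nfolds)),
            class = "solver_spec")
}

SOLVER_METHODS <- c("llsr", "qp", "ridge", "lasso", "elastic_net", "nu_svr")

#' Unconstrained linear least squares deconvolution
#'
#' Ordinary least-squares solution of \eqn{\min_f \|S f - m\|^2} with no
#' constraints; negative coefficients are handled downstream by
#' [postprocess_fractions()].
#'
#' @param S Signature matrix, genes x cell types (genes aligned with
#'   \code{m}, at least as many genes as cell types).
#' @param m Mixture expression vector.
#' @return Numeric coefficient vector, one entry per cell type.
#' @export
solve_llsr <- function(S, m) {
  check_system(S, m)
  qrS <- qr(S)
  if (qrS$rank < ncol(S)) {
    bad <- colnames(S)[qrS$pivot[(qrS$rank + 1L):ncol(S)]]
    stop("signature matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  stats::setNames(qr.coef(qrS, m), colnames(S))
}

#' Simplex-constrained quadratic programming deconvolution
#'
#' Minimizes \eqn{\|S f - m\|^2} subject to \eqn{f \ge 0} and
#' \eqn{\sum_c f_c = 1}, so the solution is a proportion vector directly and
#' needs no post-hoc renormalization.
#'
#' @inheritParams solve_llsr
#' @return Fraction vector on the simplex.
#' @export
solve_qp <- function(S, m) {
  check_system(S, m)
  k <- ncol(S)
  # rescale the system so solve.QP's Cholesky factorization stays
  # well-conditioned on CPM-scale inputs; the argmin is scale-invariant
  sc <- max(abs(S))
  if (sc <= 0) stop("signature matrix is all zero")
  S <- S / sc
  m <- m / sc
  D <- crossprod(S)
  # tiny ridge keeps the Goldfarb-Idnani factorization stable without
  # moving the optimum beyond ~1e-9
  D <- D + diag(1e-10 * mean(diag(D)), k)
  d <- crossprod(S, m)
  A <- cbind(rep(1, k), diag(k))
  b <- c(1, rep(0, k))
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = D, dvec = d, Amat = A, bvec = b, meq = 1),
    error = function(e) stop("QP solver failed: ", conditionMessage(e)))
  f <- pmax(sol$solution, 0)
  f <- f / sum(f)  # remove numerical drift from the equality constraint
  stats::setNames(f, colnames(S))
}

#' Penalized regression deconvolution (ridge / lasso / elastic net)
#'
#' Minimizes \eqn{\|S f - m\|^2 / 2n + \lambda P(f)} with the ridge, lasso
#' or elastic-net (mixing 0.5) penalty on standardized inputs. Unless a
#' fixed \code{lambda} is supplied, lambda is chosen by k-fold
#' cross-validation over genes minimizing reconstruction MSE; folds are
#' derived deterministically from the seed and the gene IDs' sort order, so
#' the result is invariant to gene-row permutations.
#'
#' @inheritParams solve_llsr
#' @param method \code{"ridge"}, \code{"lasso"} or \code{"elastic_net"}.
#' @param spec A [solver_spec()].
#' @return Coefficient vector with attribute \code{lambda} (the penalty
#'   used).
#' @export
solve_penalized <- function(S, m, method = c("ridge", "lasso", "elastic_net"),
                            spec = solver_spec(method)) {
  method <- match.arg(method)
  check_system(S, m)
  alpha <- switch(method, ridge = 0, lasso = 1, elastic_net = 0.5)
  grid <- spec$lambda_grid
  if (!is.null(spec$lambda)) {
    grid <- sort(unique(c(grid, spec$lambda)), decreasing = TRUE)
  }
  fit <- glmnet::glmnet(x = S, y = m, alpha = alpha, lambda = grid,
                        intercept = FALSE, standardize = TRUE,
                        thresh = 1e-12)
  if (is.null(spec$lambda)) {
    foldid <- gene_foldid(rownames(S), spec$nfolds, spec$seed)
    cv <- glmnet::cv.glmnet(x = S, y = m, alpha = alpha, lambda = grid,
                            intercept = FALSE, standardize = TRUE,
                            foldid = foldid, thresh = 1e-12)
    lambda <- cv$lambda.min
  } else {
    lambda <- spec$lambda
  }
  w <- as.numeric(stats::coef(fit, s = lambda))[-1]  # drop intercept row
  if (all(!is.finite(w))) stop("penalized fit degenerate at every lambda")
  structure(stats::setNames(w, colnames(S)), lambda = lambda)
}

# Deterministic CV fold assignment that depends on genes only through the
# sort order of their IDs, making solver output invariant to row permutation.
gene_foldid <- function(gene_ids, nfolds, seed) {
  n <- length(gene_ids)
  if (is.null(gene_ids)) gene_ids <- as.character(seq_len(n))
  labels <- withr::with_seed(seed, sample(rep_len(seq_len(nfolds), n)))
  labels[match(gene_ids, sort(gene_ids))]
}

#' nu-support-vector regression deconvolution
#'
#' The CIBERSORT-style protocol: genes are the observations and cell-type
#' columns the features; the signature matrix is standardized globally (one
#' mean and one SD over all entries, which preserves the relative scale of
#' the cell-type columns under the mixing model) and the mixture is z-scored
#' over genes; a linear-kernel nu-SVR is fitted for each nu in the grid, and
#' the nu minimizing root-mean-square error between fitted values and the
#' z-scored mixture is selected. The primal weight vector over cell types is
#' returned.
#'
#' @inheritParams solve_llsr
#' @param spec A [solver_spec()] (uses \code{nu_grid} and \code{cost}).
#' @return Coefficient vector with attributes \code{nu} (selected value) and
#'   \code{rmses} (named RMSE per candidate nu).
#' @export
solve_nu_svr <- function(S, m, spec = solver_spec("nu_svr")) {
  check_system(S, m)
  if (nrow(S) < 3) stop("nu-SVR needs >= 3 genes")
  if (stats::sd(m) == 0) stop("mixture vector has zero variance")
  Sz <- standardize_signature(S)
  mz <- as.numeric(scale(m))
  fits <- lapply(spec$nu_grid, function(nu) {
    # tight termination tolerance so the fitted weights do not depend on
    # the order of the gene rows
    e1071::svm(x = Sz, y = mz, type = "nu-regression", kernel = "linear",
               nu = nu, cost = spec$cost, scale = FALSE, tolerance = 1e-9)
  })
  rmses <- vapply(fits, function(f) {
    sqrt(mean((f$fitted - mz)^2))
  }, numeric(1))
  names(rmses) <- paste0("nu=", spec$nu_grid)
  best <- which.min(rmses)
  model <- fits[[best]]
  w <- drop(t(model$coefs) %*% model$SV)
  structure(stats::setNames(w, colnames(S)),
            nu = spec$nu_grid[best], rmses = rmses)
}

check_system <- function(S, m) {
  if (!is.matrix(S)) stop("S must be a matrix (genes x cell types)")
  if (length(m) != nrow(S)) stop("mixture length does not match signature gene count")
  if (nrow(S) < ncol(S)) stop("need at least as many genes as cell types")
  invisible(TRUE)
}

#' Map raw solver coefficients onto the simplex
#'
#' Negative entries are clamped to zero and the vector is divided by its
#' sum, the standard convention for reporting relative proportions. An
#' all-nonpositive input yields the all-zero vector flagged degenerate
#' rather than an error.
#'
#' @param w Raw coefficient vector (one entry per cell type).
#' @return Fraction vector with attribute \code{degenerate} (logical).
#' @export
postprocess_fractions <- function(w) {
  f <- pmax(as.numeric(w), 0)
  s <- sum(f)
  if (s <= 0) {
    return(structure(stats::setNames(rep(0, length(w)), names(w)),
                     degenerate = TRUE))
  }
  structure(stats::setNames(f / s, names(w)), degenerate = FALSE)
}

#' Deconvolute cell-type fractions from bulk expression profiles
#'
#' For each mixture sample: (optionally) quantile-normalize onto the signature
#' bundle's training reference distribution, restrict mixture and signature to
#' their shared genes, estimate raw cell-type coefficients with the requested
#' method, and map them onto the simplex ([postprocess_fractions()]; the QP
#' solution is already a proportion vector and passes through). Per-sample
#' failures are recorded in the output rather than aborting the batch.
#'
#' @param mixtures Expression matrix, genes x samples (a single vector is
#'   treated as one sample).
#' @param signature A \code{celldecon_signature}, a bundle list from
#'   [read_signature_bundle()], a bundle directory path, or a plain
#'   genes-x-cell-types matrix.
#' @param spec A [solver_spec()] naming the method.
#' @param normalize \code{"reference"} (default; quantile-normalize mixtures
#'   onto the bundle's training reference — requires the mixture to have the
#'   same gene count as the reference) or \code{"none"}.
#' @return data.frame of class \code{celldecon_fractions}: one row per
#'   sample with \code{sample_id}, one column per cell type, reconstruction
#'   \code{rmse} and \code{pcc} on the solver's working scale,
#'   \code{hyperparam} (chosen nu or lambda, NA otherwise),
#'   \code{degenerate} and \code{error} flags.
#' @export
deconvolve <- function(mixtures, signature, spec = solver_spec("nu_svr"),
                       normalize = c("reference", "none")) {
  normalize <- match.arg(normalize)
  if (!inherits(spec, "solver_spec")) stop("spec must be a solver_spec()")
  bundle <- as_signature_bundle(signature)
  if (is.null(dim(mixtures))) {
    mixtures <- matrix(mixtures, ncol = 1,
                       dimnames = list(names(mixtures), "sample_1"))
  }
  if (normalize == "reference") {
    if (is.null(bundle$reference)) {
      stop("signature bundle carries no reference distribution; use normalize = 'none'")
    }
    mixtures <- quantile_normalize(mixtures, bundle$reference)
  }
  aligned <- align_genes(mixtures, bundle$signature)
  S <- aligned$signature
  M <- aligned$mixture
  types <- colnames(S)

  rows <- lapply(seq_len(ncol(M)), function(j) {
    m <- M[, j]
    res <- tryCatch(
      deconvolve_one(S, m, spec),
      error = function(e) list(frac = rep(NA_real_, length(types)),
                               rmse = NA_real_, pcc = NA_real_,
                               hyperparam = NA_real_, degenerate = NA,
                               error = conditionMessage(e)))
    if (is.null(res$error)) res$error <- NA_character_
    c(list(sample_id = colnames(M)[j]),
      stats::setNames(as.list(res$frac), types),
      list(rmse = res$rmse, pcc = res$pcc, hyperparam = res$hyperparam,
           degenerate = res$degenerate, error = res$error))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  structure(out, cell_types = types, method = spec$method,
            n_dropped_genes = aligned$n_dropped,
            class = c("celldecon_fractions", "data.frame"))
}

deconvolve_one <- function(S, m, spec) {
  hyper <- NA_real_
  if (spec$method == "qp") {
    f <- solve_qp(S, m)
    fitted <- drop(S %*% f)
    target <- m
    degenerate <- FALSE
  } else {
    w <- switch(spec$method,
      llsr = solve_llsr(S, m),
      ridge = ,
      lasso = ,
      elastic_net = {
        ww <- solve_penalized(S, m, spec$method, spec)
        hyper <- attr(ww, "lambda")
        ww
      },
      nu_svr = {
        ww <- solve_nu_svr(S, m, spec)
        hyper <- attr(ww, "nu")
        ww
      },
      stop("unknown method: ", spec$method))
    if (spec$method == "nu_svr") {
      fitted <- drop(standardize_signature(S) %*% as.numeric(w))
      target <- as.numeric(scale(m))
    } else {
      fitted <- drop(S %*% as.numeric(w))
      target <- m
    }
    f <- postprocess_fractions(w)
    degenerate <- attr(f, "degenerate")
  }
  pcc <- if (stats::sd(fitted) > 0 && stats::sd(target) > 0) {
    stats::cor(fitted, target)
  } else NA_real_
  list(frac = as.numeric(f), rmse = sqrt(mean((fitted - target)^2)),
       pcc = pcc, hyperparam = hyper, degenerate = degenerate, error = NULL)
}

standardize_signature <- function(S) {
  s <- stats::sd(as.vector(S))
  if (s == 0) stop("signature matrix has zero variance")
  (S - mean(S)) / s
}

as_signature_bundle <- function(signature) {
  if (inherits(signature, "celldecon_signature")) {
    return(list(signature = signature$signature, reference = signature$reference))
  }
  if (is.character(signature) && length(signature) == 1) {
    return(read_signature_bundle(signature))
  }
  if (is.list(signature) && !is.null(signature$signature)) {
    return(signature)
  }
  if (is.matrix(signature)) {
    return(list(signature = signature, reference = NULL))
  }
  stop("unrecognized signature object")
}

#' Extract the samples-x-cell-types fraction matrix
#'
#' @param fractions A \code{celldecon_fractions} data.frame from
#'   [deconvolve()].
#' @return Numeric matrix, samples x cell types.
#' @export
fraction_matrix <- function(fractions) {
  types <- attr(fractions, "cell_types")
  mat <- as.matrix(fractions[, types, drop = FALSE])
  rownames(mat) <- fractions$sample_id
  mat
}
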