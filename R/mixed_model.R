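#' Build design matrices for the animal model
#'
#' Model: `y = X beta + W a + e` with fixed effects overall mean, farm,
#' lactation and parity (treatment-coded: the first level of each factor is
#' absorbed into the mean) and one random additive effect per pedigree
#' animal. A factor with a single observed level is dropped with a warning,
#' since its effect is confounded with the mean.
#'
#' @param ph a phenotype table ([read_phenotypes()] layout).
#' @param ped a [pedigree]; every record's animal must appear in it.
#' @param trait trait name to extract.
#' @return List with `y`, `X` (records x fixed-effect levels), `W` (records
#'   x pedigree animals incidence), `animal_ids` (pedigree order) and
#'   `record_animals`.
#' @export
build_design <- function(ph, ped, trait) {
  rows <- ph[ph$trait == trait, , drop = FALSE]
  if (!nrow(rows)) stop("no records for trait '", trait, "'")
  missing_ids <- setdiff(rows$animal, ped$animal)
  if (length(missing_ids)) {
    stop("record animal(s) not in pedigree: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  terms <- character(0)
  for (fac in c("farm", "lactation", "parity")) {
    if (length(unique(rows[[fac]])) > 1L) {
      terms <- c(terms, fac)
      rows[[fac]] <- factor(rows[[fac]])
    } else {
      warning("fixed effect '", fac, "' has a single level; dropped")
    }
  }
  fml <- if (length(terms)) {
    stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  } else {
    ~1
  }
  X <- stats::model.matrix(fml, data = rows)
  n <- nrow(rows)
  W <- matrix(0, n, nrow(ped), dimnames = list(NULL, ped$animal))
  W[cbind(seq_len(n), match(rows$animal, ped$animal))] <- 1
  list(y = rows$value, X = X, W = W, animal_ids = ped$animal,
       record_animals = rows$animal)
}

#' Solve the mixed-model equations
#'
#' Henderson's MME for the animal model at fixed variance components:
#' \deqn{[X'X, X'W; W'X, W'W + k H^{-1}] [\beta; a] = [X'y; W'y]}
#' with `k = sigma2_e / sigma2_a`. Solved by dense factorisation; breeding
#' values are returned for every pedigree animal (genomic EBVs for
#' genotyped animals when H carries genomic information).
#'
#' @param d design list from [build_design()].
#' @param Hinv relationship inverse over all pedigree animals (plain A
#'   inverse for a pedigree-only run, or [h_inverse()]).
#' @param vc list with positive `sigma2_a` and `sigma2_e`.
#' @return A `model_fit` list: `beta_hat`, `a_hat` (named, pedigree order),
#'   `vc`, and the relative solve residual.
#' @export
solve_mme <- function(d, Hinv, vc) {
  stopifnot(vc$sigma2_a > 0, vc$sigma2_e > 0)
  k <- vc$sigma2_e / vc$sigma2_a
  X <- d$X; W <- d$W; y <- d$y
  C <- rbind(cbind(crossprod(X), crossprod(X, W)),
             cbind(crossprod(W, X), crossprod(W) + k * unclass(Hinv)))
  rhs <- c(crossprod(X, y), crossprod(W, y))
  sol <- tryCatch(solve(C, rhs), error = function(e) {
    qrC <- qr(C)
    bad <- colnames(cbind(X, W))[qrC$pivot[-seq_len(qrC$rank)]]
    stop("mixed-model equations singular; confounded columns: ",
         paste(utils::head(bad, 10), collapse = ", "))
  })
  resid <- sqrt(sum((C %*% sol - rhs)^2)) / max(sqrt(sum(rhs^2)), 1e-300)
  p <- ncol(X)
  beta_hat <- stats::setNames(sol[seq_len(p)], colnames(X))
  a_hat <- stats::setNames(sol[-seq_len(p)], d$animal_ids)
  structure(list(beta_hat = beta_hat, a_hat = a_hat, vc = vc,
                 solve_residual = resid),
            class = "model_fit")
}

#' Gibbs sampler for variance components of the animal model
#'
#' Conjugate Gibbs with two blocks: (beta, a) are drawn jointly from their
#' multivariate-normal full conditional (mean = the MME solution at the
#' current variance ratio, covariance = C^-1 sigma2_e), then sigma2_a and
#' sigma2_e from scaled inverse chi-square full conditionals with scales
#' `a' H^-1 a` and `e'e` under flat priors (degrees of belief -2). The
#' returned fit carries posterior means of all parameters.
#'
#' @param d design list from [build_design()].
#' @param Hinv relationship inverse over all pedigree animals.
#' @param cfg a [run_config] supplying `chain_length`, `burn_in`, `thin`
#'   and `seed`.
#' @param start optional starting variance components; defaults to an even
#'   split of the phenotypic variance.
#' @return List with `chain` (data frame of thinned post-burn-in samples of
#'   sigma2_a, sigma2_e and h2, plus effective sample sizes as attributes)
#'   and `fit` (a `model_fit` of posterior means).
#' @export
gibbs_vc <- function(d, Hinv, cfg = run_config(), start = NULL) {
  set.seed(cfg$seed)
  X <- d$X; W <- d$W; y <- d$y
  n <- length(y); p <- ncol(X); q <- ncol(W)
  Hmat <- unclass(Hinv)
  XtX <- crossprod(X); XtW <- crossprod(X, W); WtW <- crossprod(W)
  rhs <- c(crossprod(X, y), crossprod(W, y))
  vy <- stats::var(y)
  sigma2_a <- if (is.null(start)) vy / 2 else start$sigma2_a
  sigma2_e <- if (is.null(start)) vy / 2 else start$sigma2_e

  n_keep <- (cfg$chain_length - cfg$burn_in) %/% cfg$thin
  samples <- matrix(NA_real_, n_keep, 2,
                    dimnames = list(NULL, c("sigma2_a", "sigma2_e")))
  iters <- integer(n_keep)
  theta_sum <- numeric(p + q)
  n_post <- 0L
  kk <- 0L
  pidx <- seq_len(p)
  aidx <- p + seq_len(q)
  C <- matrix(0, p + q, p + q)
  C[pidx, pidx] <- XtX
  C[pidx, aidx] <- XtW
  C[aidx, pidx] <- t(XtW)
  for (it in seq_len(cfg$chain_length)) {
    k <- sigma2_e / sigma2_a
    C[aidx, aidx] <- WtW + k * Hmat
    R <- chol(C)
    mu <- backsolve(R, forwardsolve(t(R), rhs))
    theta <- mu + sqrt(sigma2_e) * backsolve(R, stats::rnorm(p + q))
    a <- theta[-seq_len(p)]
    # flat priors: df = q - 2 and n - 2
    sigma2_a <- drop(crossprod(a, Hmat %*% a)) / stats::rchisq(1, q - 2)
    e <- y - X %*% theta[seq_len(p)] - W %*% a
    sigma2_e <- drop(crossprod(e)) / stats::rchisq(1, n - 2)
    if (it > cfg$burn_in) {
      theta_sum <- theta_sum + theta
      n_post <- n_post + 1L
      if ((it - cfg$burn_in) %% cfg$thin == 0L && kk < n_keep) {
        kk <- kk + 1L
        samples[kk, ] <- c(sigma2_a, sigma2_e)
        iters[kk] <- it
      }
    }
  }
  samples <- samples[seq_len(kk), , drop = FALSE]
  chain <- data.frame(iter = iters[seq_len(kk)], samples,
                      h2 = samples[, 1] / rowSums(samples))
  ess_a <- ess(chain$sigma2_a)
  if (is.finite(ess_a) && ess_a < 50) {
    warning("effective sample size of sigma2_a is ", round(ess_a, 1),
            " (< 50); consider a longer chain")
  }
  attr(chain, "ess") <- c(sigma2_a = ess_a, sigma2_e = ess(chain$sigma2_e))
  theta_mean <- theta_sum / n_post
  vc <- list(sigma2_a = mean(chain$sigma2_a),
             sigma2_e = mean(chain$sigma2_e))
  fit <- structure(list(
    beta_hat = stats::setNames(theta_mean[seq_len(p)], colnames(X)),
    a_hat = stats::setNames(theta_mean[-seq_len(p)], d$animal_ids),
    vc = vc,
    posterior = list(
      mean = vapply(chain[-1], mean, numeric(1)),
      sd = vapply(chain[-1], stats::sd, numeric(1)),
      ess = attr(chain, "ess"))
  ), class = "model_fit")
  list(chain = chain, fit = fit)
}

# Effective sample size from the autocorrelation function (initial positive
# sequence truncation).
ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(NA_real_)
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1L] - 1L)]
  n / (1 + 2 * sum(rho))
}
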