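#' @include AllClasses.R
NULL

#' Additive and dominance genomic relationship matrices
#'
#' The additive GRM averages centred-scaled dosage codes
#' \eqn{(x - 2p)/\sqrt{2p(1-p)}} over SNPs; the dominance GRM uses the
#' orthogonal coding (hom-ref, het, hom-alt) =
#' \eqn{(-2p^2,\; 2p(1-p),\; -2(1-p)^2)} scaled by \eqn{2p(1-p)} per SNP so
#' that the expected diagonal is 1 under Hardy-Weinberg. Under HWE the two
#' codings are orthogonal per variant, which is what lets the two variance
#' components be estimated simultaneously. Monomorphic variants are excluded
#' with a warning; missing dosages are mean-imputed at this (model-fitting)
#' stage.
#'
#' @param geno a \linkS4class{GenotypeData} (or plain dosage matrix).
#' @param freqs optional per-variant alternate-allele frequencies; estimated
#'   from the sample when omitted.
#' @return list of class \code{GRMPair}: \code{Ga}, \code{Gd} (n x n),
#'   \code{nSnps}.
#' @export
buildGRMs <- function(geno, freqs = NULL) {
  m <- if (is(geno, "GenotypeData")) dosages(geno) else geno
  storage.mode(m) <- "double"
  if (is.null(freqs)) freqs <- colMeans(m, na.rm = TRUE) / 2
  poly <- freqs > 0 & freqs < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic variant(s) excluded from the GRMs")
    m <- m[, poly, drop = FALSE]
    freqs <- freqs[poly]
  }
  nsnp <- ncol(m)
  if (anyNA(m)) {
    for (j in which(colSums(is.na(m)) > 0))
      m[is.na(m[, j]), j] <- 2 * freqs[j]
  }
  p <- freqs
  het <- 2 * p * (1 - p)
  Za <- sweep(sweep(m, 2, 2 * p), 2, sqrt(het), "/")
  Ga <- tcrossprod(Za) / nsnp
  # orthogonal dominance codes by genotype class; E[code^2] = (2pq)^2 under
  # HWE, so dividing by sum((2pq)^2) gives expected diagonal 1
  Zd <- matrix(0, nrow(m), nsnp)
  cls <- col(m)
  Zd[m == 0] <- (-2 * p^2)[cls[m == 0]]
  Zd[m == 1] <- (2 * p * (1 - p))[cls[m == 1]]
  Zd[m == 2] <- (-2 * (1 - p)^2)[cls[m == 2]]
  # mean-imputed (fractional) entries approximate the het code weighted by
  # the residual heterozygosity; they are rare and contribute ~0
  Gd <- tcrossprod(Zd) / sum(het^2)
  structure(list(Ga = Ga, Gd = Gd, nSnps = nsnp), class = "GRMPair")
}

#' Additive + dominance REML (GREMLd)
#'
#' Maximises the restricted likelihood of
#' \eqn{y \sim N(1\mu,\; G_a\sigma^2_a + G_d\sigma^2_d + I\sigma^2_e)} by
#' average-information (AI) iterations, falling back to an EM step whenever
#' the AI proposal leaves the parameter space (EM never decreases the
#' restricted likelihood). Components are constrained non-negative by
#' projection to a small positive boundary. Standard errors come from the
#' inverse AI matrix at convergence, with the delta method for the ratios
#' \eqn{h^2} and \eqn{\delta^2}.
#'
#' @param y numeric phenotype vector, or a \code{PhenotypeTable} (its
#'   \code{y} column is used; record-count weights are not used here, the
#'   residual is homoscedastic).
#' @param grms a \code{GRMPair} from \code{\link{buildGRMs}}.
#' @param init optional starting values \code{c(a, d, e)}.
#' @param maxIter,tol convergence controls (successive restricted
#'   log-likelihood change below \code{tol}).
#' @param verbose print the iteration trace.
#' @return a \linkS4class{VarianceComponents}.
#' @export
remlAD <- function(y, grms, init = NULL, maxIter = 100, tol = 1e-6,
                   verbose = FALSE) {
  if (is.data.frame(y)) y <- y$y
  stopifnot(!anyNA(y))
  n <- length(y)
  G <- list(a = grms$Ga, d = grms$Gd, e = diag(n))
  stopifnot(nrow(grms$Ga) == n, nrow(grms$Gd) == n)
  vy <- stats::var(y)
  s2 <- if (is.null(init)) c(a = 0.4, d = 0.1, e = 0.5) * vy else
    stats::setNames(init, c("a", "d", "e"))
  lb <- 1e-8 * vy
  X <- matrix(1, n, 1)
  restricted <- function(s2) {
    V <- s2[1] * G$a + s2[2] * G$d + s2[3] * G$e
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      ch <- tryCatch(chol(V + diag(1e-6 * mean(diag(V)), n)),
                     error = function(e) NULL)
      if (is.null(ch)) return(NULL)
    }
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    P <- Vi - ViX %*% solve(XtViX, t(ViX))
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX)$modulus[1] +
                    sum(y * Py))
    list(P = P, Py = Py, ll = as.numeric(ll))
  }
  st <- restricted(s2)
  if (is.null(st)) stop("initial covariance matrix is not positive definite")
  trace <- data.frame(iter = 0, logLik = st$ll, a = s2[1], d = s2[2],
                      e = s2[3], step = "init")
  converged <- FALSE
  AI <- NULL
  for (it in seq_len(maxIter)) {
    Py <- st$Py
    t_ <- lapply(G, function(g) g %*% Py)
    dl <- vapply(seq_along(G), function(k)
      -0.5 * (sum(st$P * G[[k]]) - sum(Py * t_[[k]])), numeric(1))
    AI <- matrix(0, 3, 3)
    Pt <- lapply(t_, function(tk) st$P %*% tk)
    for (i in 1:3) for (j in i:3)
      AI[i, j] <- AI[j, i] <- 0.5 * sum(t_[[i]] * Pt[[j]])
    emProp <- pmax(vapply(1:3, function(k)
      s2[k] + (s2[k]^2 / n) * (sum(Py * t_[[k]]) - sum(st$P * G[[k]])),
      numeric(1)), lb)
    # components stuck at the lower boundary with a negative gradient are
    # held there and dropped from the AI system (active-set update)
    active <- !(s2 <= lb * 1.01 & dl < 0)
    aiProp <- s2
    if (any(active)) {
      step <- tryCatch(solve(AI[active, active, drop = FALSE], dl[active]),
                       error = function(e) rep(NA, sum(active)))
      aiProp[active] <- s2[active] + step
    }
    stepType <- "AI"
    # negative AI proposals are projected onto the boundary; the halving
    # guard below rejects projections that hurt the restricted likelihood
    prop <- aiProp
    stNew <- NULL
    if (!anyNA(prop)) {
      prop <- pmax(prop, lb)
      stNew <- restricted(prop)
      tries <- 0
      # halve AI steps that leave the PD cone or decrease the likelihood
      while ((is.null(stNew) || stNew$ll < st$ll - 1e-10) && tries < 5) {
        prop <- (s2 + prop) / 2
        stNew <- restricted(prop)
        tries <- tries + 1
      }
      if (is.null(stNew) || stNew$ll < st$ll - 1e-10) stNew <- NULL
    }
    if (is.null(stNew)) {
      # EM fallback: monotone in the restricted likelihood
      stepType <- "EM"
      prop <- emProp
      stNew <- restricted(prop)
      if (is.null(stNew)) {
        prop <- (s2 + prop) / 2
        stNew <- restricted(prop)
        if (is.null(stNew))
          stop("covariance matrix not positive definite after jitter retry")
      }
    }
    delta <- abs(stNew$ll - st$ll)
    maxRel <- max(abs(prop - s2) / (abs(s2) + lb))
    s2 <- stats::setNames(prop, c("a", "d", "e"))
    st <- stNew
    trace <- rbind(trace, data.frame(iter = it, logLik = st$ll, a = s2[1],
                                     d = s2[2], e = s2[3], step = stepType))
    if (verbose)
      message(sprintf("iter %d [%s] logLik %.6f  a=%.4g d=%.4g e=%.4g",
                      it, stepType, st$ll, s2[1], s2[2], s2[3]))
    if (delta < tol || maxRel < 1e-8) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("REML did not converge in ", maxIter, " iterations")
  }
  covm <- tryCatch(solve(AI), error = function(e) matrix(NA, 3, 3))
  se <- sqrt(pmax(diag(covm), 0))
  tot <- sum(s2)
  ratioSe <- function(k) {
    # delta method for s2[k] / sum(s2)
    gr <- -s2[k] / tot^2 * rep(1, 3)
    gr[k] <- gr[k] + 1 / tot
    sqrt(max(0, drop(t(gr) %*% covm %*% gr)))
  }
  new("VarianceComponents",
      sigma2 = s2, se = stats::setNames(se, c("a", "d", "e")),
      h2 = unname(s2["a"] / tot), delta2 = unname(s2["d"] / tot),
      seH2 = ratioSe(1), seDelta2 = ratioSe(2),
      logLik = st$ll, converged = converged, trace = trace)
}

#' Write a variance-component report
#'
#' One row per trait/stratum with columns mirroring the usual heritability
#' table: h2, its SE, delta2, its SE, and the raw components.
#'
#' @param vc a \linkS4class{VarianceComponents} or named list of them.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeVarianceReport <- function(vc, path) {
  if (is(vc, "VarianceComponents")) vc <- list(trait = vc)
  rows <- do.call(rbind, lapply(names(vc), function(nm) {
    v <- vc[[nm]]
    data.frame(trait = nm, h2 = v@h2, seH2 = v@seH2, delta2 = v@delta2,
               seDelta2 = v@seDelta2, sigma2a = v@sigma2["a"],
               sigma2d = v@sigma2["d"], sigma2e = v@sigma2["e"],
               converged = v@converged)
  }))
  data.table::fwrite(rows, path, sep = "\t")
  invisible(path)
}
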