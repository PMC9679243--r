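# Multistate IPM kernel assembly.
#
# The annual kernel is a 3x3 block matrix over the discrete states
# {NORMAL, BOLTER, DORMANT}; each block is an n x n matrix over a shared
# midpoint-rule size mesh. Bolters and dormant plants have no measurable
# rosette, so their blocks use latent-size memory: an individual occupies
# the mesh cell of its last measured NORMAL diameter, which keeps the full
# n x n block structure and lets transitions out of the sizeless states be
# size-dependent when model selection warrants it.

.kernel_states <- c("NORMAL", "BOLTER", "DORMANT")

#' Build a midpoint-rule size mesh
#'
#' The mesh spans 0 mm to 110\% of the largest observed rosette diameter,
#' with \code{n_points} cells of width \code{h} and midpoints
#' \code{z_i = (i - 0.5) h}.
#'
#' @param max_observed_diameter Largest observed rosette diameter (mm).
#' @param n_points Number of mesh cells (default 150).
#' @return Object of class \code{mesh_grid} with elements \code{n_points},
#'   \code{lower}, \code{upper}, \code{h}, \code{z} (midpoints).
#' @export
buildMesh <- function(max_observed_diameter, n_points = 150L) {
  if (!is.finite(max_observed_diameter) || max_observed_diameter <= 0)
    stop("max_observed_diameter must be positive")
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("n_points must be >= 2")
  upper <- 1.1 * max_observed_diameter
  h <- upper / n_points
  structure(list(n_points = n_points, lower = 0, upper = upper, h = h,
                 z = (seq_len(n_points) - 0.5) * h),
            class = "mesh_grid")
}

#' @export
print.mesh_grid <- function(x, ...) {
  cat("Size mesh: ", x$n_points, " cells on [0, ", signif(x$upper, 5),
      "] mm (h = ", signif(x$h, 5), ")\n", sep = "")
  invisible(x)
}

# column-normalized Gaussian growth operator on the mesh: entry [i, j] is the
# probability a survivor of size z_j has next-year size in cell i. Mass that
# falls outside the mesh (eviction) is returned by renormalizing the
# truncated column; a column with no mass on the mesh collapses to the
# nearest boundary cell.
.growth_matrix <- function(mesh, mu, sd) {
  n <- mesh$n_points
  if (sd <= 0) {  # point-mass growth: nearest cell
    G <- matrix(0, n, n)
    idx <- pmin(pmax(ceiling(mu / mesh$h), 1L), n)
    G[cbind(idx, seq_len(n))] <- 1
    return(G)
  }
  G <- outer(mesh$z, mu, function(zp, m) dnorm(zp, m, sd)) * mesh$h
  cs <- colSums(G)
  lost <- cs < 1e-12
  if (any(lost)) {
    idx <- ifelse(mu[lost] < mesh$lower, 1L, n)
    G[, lost] <- 0
    G[cbind(idx, which(lost))] <- 1
    cs[lost] <- 1
  }
  sweep(G, 2L, cs, "/")
}

# normalized recruit-size density over the mesh (Normal truncated to mesh)
.recruit_density <- function(mesh, mu, sd) {
  if (sd <= 0) {
    v <- numeric(mesh$n_points)
    v[pmin(pmax(ceiling(mu / mesh$h), 1L), mesh$n_points)] <- 1
    return(v)
  }
  v <- dnorm(mesh$z, mu, sd) * mesh$h
  s <- sum(v)
  if (s < 1e-12) stop("recruit size distribution has no mass on the mesh")
  v / s
}

#' Assemble a multistate IPM kernel from coefficient functions
#'
#' Low-level assembler shared by the truth-kernel oracle and the fitted
#' pathway. \code{coefs} holds link-scale coefficient vectors
#' \code{c(intercept, size, size^2)} for every vital rate plus the scalars
#' \code{growth_sd}, \code{recruit_rate}, \code{recruit_mu},
#' \code{recruit_sd}. \code{delta} adds a per-rate intercept shift (the
#' realized year deviation) on the link scale.
#'
#' @param coefs Named list of coefficients (see Details in the vignette).
#' @param mesh A [buildMesh()] grid.
#' @param delta Named numeric of year-intercept shifts; missing names are 0.
#' @param population,label Metadata stored on the kernel.
#' @return Object of class \code{ipm_kernel}: the mesh, the 3x3 named block
#'   list, the assembled \code{(3n) x (3n)} matrix, and metadata.
#' @export
assembleKernel <- function(coefs, mesh, delta = NULL, population = NA_character_,
                           label = NA_character_) {
  stopifnot(inherits(mesh, "mesh_grid"))
  need <- c(.rate_names, "growth_sd", "recruit_rate", "recruit_mu", "recruit_sd")
  miss <- setdiff(need, names(coefs))
  if (length(miss)) stop("assembleKernel: missing coefficients: ",
                         paste(miss, collapse = ", "))
  d <- setNames(numeric(length(.rate_names)), .rate_names)
  if (!is.null(delta)) d[names(delta)] <- delta
  z <- mesh$z
  n <- mesh$n_points
  # vital-rate functions are clamped to the size support they were fitted
  # on (constant extrapolation), so unsupported mesh cells cannot blow up
  eta <- function(rate) {
    zr <- z
    rng <- attr(coefs[[rate]], "size_range")
    if (!is.null(rng)) zr <- pmin(pmax(z, rng[1]), rng[2])
    .lp(coefs[[rate]], zr) + d[[rate]]
  }
  sN <- plogis(eta("surv_N")); sB <- plogis(eta("surv_B")); sD <- plogis(eta("surv_D"))
  pNB <- plogis(eta("trans_NB")); pND <- plogis(eta("trans_ND"))
  pBN <- plogis(eta("trans_BN")); pBD <- plogis(eta("trans_BD"))
  pDN <- plogis(eta("trans_DN")); pDB <- plogis(eta("trans_DB"))
  norm_pair <- function(a, b) {
    tot <- a + b
    f <- ifelse(tot > 1, 1 / tot, 1)
    list(a * f, b * f)
  }
  nb <- norm_pair(pNB, pND); pNB <- nb[[1]]; pND <- nb[[2]]
  bb <- norm_pair(pBN, pBD); pBN <- bb[[1]]; pBD <- bb[[2]]
  db <- norm_pair(pDN, pDB); pDN <- db[[1]]; pDB <- db[[2]]
  efN <- plogis(eta("pfl_N")) * exp(eta("fec_N"))
  efB <- plogis(eta("pfl_B")) * exp(eta("fec_B"))
  zg <- z
  grng <- attr(coefs$growth, "size_range")
  if (!is.null(grng)) zg <- pmin(pmax(z, grng[1]), grng[2])
  G <- .growth_matrix(mesh, .lp(coefs$growth, zg) + d[["growth"]], coefs$growth_sd)
  phi <- .recruit_density(mesh, coefs$recruit_mu, coefs$recruit_sd)
  rr <- coefs$recruit_rate

  colmul <- function(M, w) sweep(M, 2L, w, "*")
  stay <- function(p1, p2) pmax(0, 1 - p1 - p2)  # guard FP residue after
                                                 # pair normalization
  blocks <- list(
    NORMAL = list(
      NORMAL  = colmul(G, sN * stay(pNB, pND)) + outer(phi, efN * rr),
      BOLTER  = colmul(G, sB * pBN) + outer(phi, efB * rr),
      DORMANT = colmul(G, sD * pDN)),
    BOLTER = list(
      NORMAL  = diag(sN * pNB, n),
      BOLTER  = diag(sB * stay(pBN, pBD), n),
      DORMANT = diag(sD * pDB, n)),
    DORMANT = list(
      NORMAL  = diag(sN * pND, n),
      BOLTER  = diag(sB * pBD, n),
      DORMANT = diag(sD * stay(pDN, pDB), n)))
  mat <- matrix(0, 3L * n, 3L * n)
  for (i in 1:3) for (j in 1:3) {
    B <- blocks[[.kernel_states[i]]][[.kernel_states[j]]]
    if (any(!is.finite(B)) || any(B < 0))
      stop("non-finite or negative entries in block ",
           .kernel_states[j], " -> ", .kernel_states[i])
    mat[((i - 1L) * n + 1L):(i * n), ((j - 1L) * n + 1L):(j * n)] <- B
  }
  structure(list(mesh = mesh, blocks = blocks, mat = mat,
                 population = population, label = label),
            class = "ipm_kernel")
}

#' Extract a kernel block
#'
#' @param K An \code{ipm_kernel}.
#' @param from,to Source and destination state labels
#'   (\code{"NORMAL"}, \code{"BOLTER"}, \code{"DORMANT"}).
#' @return The \code{n x n} block matrix mapping \code{from} to \code{to}.
#' @export
kernelBlock <- function(K, from, to) {
  stopifnot(inherits(K, "ipm_kernel"),
            from %in% .kernel_states, to %in% .kernel_states)
  K$blocks[[to]][[from]]
}

#' @export
as.matrix.ipm_kernel <- function(x, ...) x$mat

#' @export
print.ipm_kernel <- function(x, ...) {
  n <- x$mesh$n_points
  cat("Multistate IPM kernel (", 3 * n, "x", 3 * n, "; mesh ", n,
      " cells to ", signif(x$mesh$upper, 4), " mm)\n", sep = "")
  if (!is.na(x$population)) cat("  population:", x$population, "\n")
  if (!is.na(x$label)) cat("  label:", x$label, "\n")
  cat("  dominant lambda:", signif(dominantLambda(x), 6), "\n")
  invisible(x)
}

#' Project a state vector through a kernel
#'
#' @param K An \code{ipm_kernel} (or a plain square matrix).
#' @param v Numeric state vector, length \code{3 n} (NORMAL, BOLTER, DORMANT
#'   segments stacked over the mesh).
#' @return The projected vector.
#' @export
applyKernel <- function(K, v) {
  M <- if (inherits(K, "ipm_kernel")) K$mat else as.matrix(K)
  if (length(v) != ncol(M))
    stop("state vector length ", length(v), " does not match kernel size ",
         ncol(M))
  drop(M %*% v)
}

#' Dominant eigenvalue by power iteration
#'
#' @param K \code{ipm_kernel} or square matrix.
#' @param tol Convergence tolerance on successive Rayleigh quotients.
#' @param max_iter Iteration cap.
#' @return The dominant eigenvalue (asymptotic annual growth rate).
#' @export
dominantLambda <- function(K, tol = 1e-12, max_iter = 10000L) {
  M <- if (inherits(K, "ipm_kernel")) K$mat else as.matrix(K)
  n <- ncol(M)
  v <- rep(1 / n, n)
  lam <- 0
  for (i in seq_len(max_iter)) {
    v1 <- drop(M %*% v)
    s <- sum(v1)
    if (s == 0) return(0)
    lam1 <- s / sum(v)
    v <- v1 / s
    if (abs(lam1 - lam) < tol * max(1, abs(lam1))) return(lam1)
    lam <- lam1
  }
  lam
}

#' Uniform initial state vector
#'
#' Equal density in every mesh cell of every live state, scaled to a total.
#'
#' @param mesh A [buildMesh()] grid.
#' @param total Total population size the vector sums to.
#' @return Numeric vector of length \code{3 n}.
#' @export
uniformStateVector <- function(mesh, total = 1) {
  n <- 3L * mesh$n_points
  rep(total / n, n)
}
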