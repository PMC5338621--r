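#' Average-reference matrix / operation
#'
#' The centering matrix `R` with `r_ll = 1 - 1/L` and `r_il = -1/L` fixes the
#' sum of the electrode voltages to zero. `average_reference()` applies it to
#' a vector or to each column of a matrix; `reference_matrix()` returns the
#' dense L x L matrix (idempotent: `R R = R`).
#'
#' @param y electrode voltage vector or L x M matrix.
#' @return same shape as `y`, re-referenced.
#' @export
average_reference <- function(y) {
  if (is.matrix(y)) {
    sweep(y, 2L, colMeans(y))
  } else {
    y - mean(y)
  }
}

#' @rdname average_reference
#' @param L number of electrodes.
#' @export
reference_matrix <- function(L) {
  diag(L) - matrix(1 / L, L, L)
}

# Jacobi-preconditioned conjugate gradients for SPD sparse A, multiple rhs.
pcg_solve <- function(A, Bmat, rtol = 1e-10, maxit = NULL) {
  N <- nrow(A)
  if (is.null(maxit)) maxit <- ceiling(10 * sqrt(N))
  d <- Matrix::diag(A)
  if (any(d <= 0)) stop("non-positive diagonal; matrix not SPD")
  Bmat <- as.matrix(Bmat)
  X <- matrix(0, N, ncol(Bmat))
  for (j in seq_len(ncol(Bmat))) {
    b <- Bmat[, j]
    nb <- sqrt(sum(b^2))
    if (nb == 0) next
    x <- numeric(N)
    r <- b
    zv <- r / d
    p <- zv
    rz <- sum(r * zv)
    for (it in seq_len(maxit)) {
      Ap <- as.numeric(A %*% p)
      alpha <- rz / sum(p * Ap)
      x <- x + alpha * p
      r <- r - alpha * Ap
      if (sqrt(sum(r^2)) <= rtol * nb) break
      zv <- r / d
      rz_new <- sum(r * zv)
      p <- zv + (rz_new / rz) * p
      rz <- rz_new
    }
    if (sqrt(sum(r^2)) > rtol * nb) {
      stop("conjugate gradients did not converge for column ", j,
           "; relative residual ", format(sqrt(sum(r^2)) / nb))
    }
    X[, j] <- x
  }
  X
}

#' Compute the lead-field matrix
#'
#' Builds the referenced L x M lead field `y = L x` mapping Whitney-dipole
#' amplitudes (A m) to average-referenced electrode voltages (V). For the CEM,
#' `L = R (B^T A^-1 B - C)^-1 B^T A^-1 G`; for the PEM, `L = R B'^T A'^-1 G`.
#' Three algebraically equivalent routes are provided for the CEM:
#'
#' * `"schur"`: sparse Cholesky factorization of `A`, transfer matrix
#'   `H = B^T A^-1` by direct solves, then the L x L Schur solve.
#' * `"transfer"`: as `"schur"` but `A H^T = B` is solved by Jacobi-
#'   preconditioned conjugate gradients (the iterative transfer-matrix
#'   route), relative tolerance `rtol`, at most `10 sqrt(N)` iterations.
#' * `"block"`: direct sparse factorization of the full block system, solved
#'   against every source column (chunked).
#'
#' @param system a `cem_system` or `pem_system`.
#' @param G N x M sparse source matrix.
#' @param method `"schur"`, `"transfer"` or `"block"` (CEM; ignored for PEM).
#' @param rtol iterative-solver tolerance for `"transfer"`.
#' @param chunk column block size for `"block"`.
#' @return object of class `lead_field`: `matrix` (L x M, volts per A m,
#'   average-referenced: every column sums to zero), `model`, `method`,
#'   `impedance` (CEM) and `reference = "average"`.
#' @export
compute_lead_field <- function(system, G,
                               method = c("schur", "transfer", "block"),
                               rtol = 1e-10, chunk = 256L) {
  method <- match.arg(method)
  if (any(!is.finite(G@x))) stop("non-finite entries in source matrix")
  if (system$model == "pem") {
    X <- as.matrix(Matrix::solve(system$A, system$B))
    # z = A'^-1 (-G x)  =>  v = -B'^T A'^-1 G x
    V <- -t(as.matrix(Matrix::crossprod(G, X)))  # L x M
    lf <- average_reference(V)
    return(structure(list(matrix = lf, model = "pem", method = "direct",
                          impedance = NULL, reference = "average"),
                     class = "lead_field"))
  }
  A <- system$A; B <- system$B
  L <- ncol(B)
  if (method == "block") {
    M <- ncol(G)
    BM <- rbind(cbind(A, -B),
                cbind(-Matrix::t(B), Matrix::Diagonal(L, system$C)))
    fac <- Matrix::lu(BM)
    V <- matrix(0, L, M)
    N <- system$n_nodes
    for (start in seq(1L, M, by = chunk)) {
      cols <- start:min(start + chunk - 1L, M)
      rhs <- rbind(-G[, cols, drop = FALSE],
                   Matrix::Matrix(0, L, length(cols), sparse = TRUE))
      S <- Matrix::solve(fac, as.matrix(rhs))
      V[, cols] <- as.matrix(S[N + seq_len(L), , drop = FALSE])
    }
  } else {
    X <- if (method == "schur") {
      as.matrix(Matrix::solve(A, B))
    } else {
      pcg_solve(A, B, rtol = rtol)
    }
    S <- Matrix::t(Matrix::crossprod(B, X)) -
      Matrix::Diagonal(L, system$C)  # B^T A^-1 B - C
    HG <- t(as.matrix(Matrix::crossprod(G, X)))           # L x M
    S <- as.matrix(S)
    if (rcond(S) < 1e-14) {
      stop("singular Schur complement; degenerate impedances or patches")
    }
    V <- solve(S, HG)
  }
  lf <- average_reference(V)
  structure(list(matrix = lf, model = "cem", method = method,
                 impedance = system$cap$impedance, reference = "average"),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat("<lead_field> ", toupper(x$model), ", ", nrow(x$matrix), " electrodes x ",
      ncol(x$matrix), " sources, ", x$reference, " reference (method: ",
      x$method, ")\n", sep = "")
  invisible(x)
}

#' Tidy view of a lead field
#' @param x a `lead_field`.
#' @param ... unused.
#' @return tibble with columns `electrode`, `source`, `gain` (V per A m).
#' @export
tidy.lead_field <- function(x, ...) {
  m <- x$matrix
  tibble::tibble(
    electrode = rep(seq_len(nrow(m)), times = ncol(m)),
    source = rep(seq_len(ncol(m)), each = nrow(m)),
    gain = as.vector(m)
  )
}

#' Export / import a lead field
#'
#' Plain-text container: a JSON header (model, method, impedances, reference,
#' dimensions) followed by the matrix in column-major order, one value per
#' line, full precision.
#'
#' @param lf a `lead_field`.
#' @param path file path.
#' @return `write_lead_field` returns `path` invisibly; `read_lead_field`
#'   returns the `lead_field`.
#' @export
write_lead_field <- function(lf, path) {
  hdr <- jsonlite::toJSON(list(model = lf$model, method = lf$method,
                               impedance = lf$impedance,
                               reference = lf$reference,
                               dim = dim(lf$matrix)),
                          auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(hdr), con)
  writeLines(sprintf("%.17g", as.vector(lf$matrix)), con)
  invisible(path)
}

#' @rdname write_lead_field
#' @export
read_lead_field <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- jsonlite::fromJSON(lines[1])
  vals <- as.numeric(lines[-1])
  structure(list(matrix = matrix(vals, nrow = hdr$dim[1], ncol = hdr$dim[2]),
                 model = hdr$model, method = hdr$method,
                 impedance = hdr$impedance, reference = hdr$reference),
            class = "lead_field")
}
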