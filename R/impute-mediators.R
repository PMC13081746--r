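#' Impute missing mediators by iterative low-rank reconstruction
#'
#' A factor-analysis-of-mixed-data (FAMD) style scheme for mixed
#' continuous/binary/ordinal tables: continuous and ordinal columns are
#' standardized, binary columns are indicator-coded with each indicator
#' scaled by the inverse square root of its column frequency (so both
#' variable kinds contribute comparable inertia), and missing cells are
#' filled by iterating SVD reconstruction at a fixed rank until
#' convergence. The rank is chosen by `cv_folds`-fold cross-validation:
#' a random fold of *observed* cells is masked, ranks `0..max_rank` are
#' fitted on the remainder, and the rank minimizing held-out
#' reconstruction error (in the encoded space) wins. Binary and ordinal
#' cells are mapped back to valid levels by nearest-level rounding;
#' observed cells are never altered.
#'
#' @param tab data.frame of mediators (numeric columns; binaries coded
#'   0/1).
#' @param types optional named character vector, entries
#'   `"continuous"`, `"binary"` or `"ordinal"`; inferred when missing
#'   (two observed values in \{0,1\} = binary; <= 12 distinct integers =
#'   ordinal).
#' @param max_rank largest rank considered (default 5, capped at
#'   dimensions - 1).
#' @param cv_folds folds for rank selection (default 10).
#' @param seed RNG seed (fold assignment); imputation is deterministic
#'   given the seed.
#' @param maxit,tol iteration control for the fixed-rank fits.
#' @return completed data.frame; attributes `"rank"` (chosen rank),
#'   `"cv_error"` (per-rank CV error) and `"types"`.
#' @export
impute_mediators <- function(tab, types = NULL, max_rank = 5, cv_folds = 10,
                             seed = NULL, maxit = 200, tol = 1e-6) {
  if (!is.data.frame(tab) || nrow(tab) == 0L || ncol(tab) == 0L) {
    stop_invalid("mediator table must be a nonempty data.frame")
  }
  if (any(colSums(!is.na(tab)) == 0L)) {
    stop_invalid("column(s) with no observed values cannot be imputed")
  }
  types <- infer_types(tab, types)

  const_cols <- vapply(tab, function(x) {
    v <- unique(x[!is.na(x)]); length(v) == 1L
  }, logical(1))
  if (any(const_cols & vapply(tab, anyNA, logical(1)))) {
    warning(
      "constant observed column(s) imputed to that constant: ",
      paste(names(tab)[const_cols & vapply(tab, anyNA, logical(1))],
            collapse = ", ")
    )
    for (v in names(tab)[const_cols]) {
      tab[[v]][is.na(tab[[v]])] <- unique(tab[[v]][!is.na(tab[[v]])])
    }
  }

  if (!anyNA(tab)) {
    attr(tab, "rank") <- 0L
    attr(tab, "types") <- types
    return(tab)
  }

  enc <- famd_encode(tab[, !const_cols, drop = FALSE],
                     types[!const_cols])
  Z <- enc$Z
  obs <- which(!is.na(Z))
  max_rank <- min(max_rank, nrow(Z) - 1L, ncol(Z) - 1L)

  cv_err <- with_seed(seed, {
    fold <- sample(rep_len(seq_len(cv_folds), length(obs)))
    err <- numeric(max_rank + 1L)
    for (r in 0:max_rank) {
      sqerr <- 0
      for (f in seq_len(cv_folds)) {
        held <- obs[fold == f]
        Ztrain <- Z
        Ztrain[held] <- NA
        rec <- svd_complete(Ztrain, r, maxit = maxit, tol = tol)
        sqerr <- sqerr + sum((rec[held] - Z[held])^2)
      }
      err[r + 1L] <- sqerr / length(obs)
    }
    err
  })
  best_rank <- which.min(cv_err) - 1L

  completed <- svd_complete(Z, best_rank, maxit = maxit, tol = tol)
  Zfull <- Z
  Zfull[is.na(Z)] <- completed[is.na(Z)]
  dec <- famd_decode(Zfull, enc)

  out <- tab
  for (v in names(dec)) {
    hole <- is.na(out[[v]])
    out[[v]][hole] <- dec[[v]][hole]
  }
  attr(out, "rank") <- best_rank
  attr(out, "cv_error") <- stats::setNames(cv_err, paste0("rank", 0:max_rank))
  attr(out, "types") <- types
  out
}

infer_types <- function(tab, types) {
  inferred <- vapply(tab, function(x) {
    v <- sort(unique(x[!is.na(x)]))
    if (length(v) <= 2L && all(v %in% c(0, 1))) return("binary")
    if (length(v) <= 12L && all(v == round(v))) return("ordinal")
    "continuous"
  }, character(1))
  if (!is.null(types)) {
    bad <- setdiff(names(types), names(tab))
    if (length(bad)) stop_invalid("unknown columns in types: ",
                                  paste(bad, collapse = ", "))
    inferred[names(types)] <- types
  }
  ok <- inferred %in% c("continuous", "binary", "ordinal")
  if (!all(ok)) stop_invalid("invalid type(s): ",
                             paste(unique(inferred[!ok]), collapse = ", "))
  inferred
}

# Encode mixed table on the FAMD-standardized scale. Continuous/ordinal:
# (x - mean) / sd. Binary: two indicators each divided by sqrt(freq) and
# centered.
famd_encode <- function(tab, types) {
  cols <- list(); map <- list()
  for (v in names(tab)) {
    x <- tab[[v]]
    if (types[[v]] == "binary") {
      p1 <- mean(x == 1, na.rm = TRUE)
      p0 <- 1 - p1
      i1 <- as.numeric(x == 1) / sqrt(p1)
      i0 <- as.numeric(x == 0) / sqrt(p0)
      cols[[paste0(v, "=1")]] <- i1 - mean(i1, na.rm = TRUE)
      cols[[paste0(v, "=0")]] <- i0 - mean(i0, na.rm = TRUE)
      map[[v]] <- list(
        type = "binary", cols = paste0(v, c("=1", "=0")),
        p1 = p1, p0 = p0,
        centers = c(mean(i1, na.rm = TRUE), mean(i0, na.rm = TRUE))
      )
    } else {
      mu <- mean(x, na.rm = TRUE)
      s <- stats::sd(x, na.rm = TRUE)
      if (!is.finite(s) || s == 0) s <- 1
      cols[[v]] <- (x - mu) / s
      lv <- if (types[[v]] == "ordinal") sort(unique(x[!is.na(x)])) else NULL
      map[[v]] <- list(type = types[[v]], cols = v, mu = mu, s = s,
                       levels = lv)
    }
  }
  list(Z = do.call(cbind, cols), map = map)
}

famd_decode <- function(Zfull, enc) {
  out <- list()
  for (v in names(enc$map)) {
    m <- enc$map[[v]]
    if (m$type == "binary") {
      # de-center the indicators and pick the level with higher
      # reconstructed (frequency-rescaled) membership
      i1 <- (Zfull[, m$cols[1]] + m$centers[1]) * sqrt(m$p1)
      i0 <- (Zfull[, m$cols[2]] + m$centers[2]) * sqrt(m$p0)
      out[[v]] <- as.numeric(i1 >= i0)
    } else {
      x <- Zfull[, m$cols] * m$s + m$mu
      if (m$type == "ordinal") {
        x <- vapply(x, function(xx) m$levels[which.min(abs(m$levels - xx))],
                    numeric(1))
      }
      out[[v]] <- x
    }
  }
  out
}

# Iterative SVD completion at fixed rank on an already-encoded matrix.
# Rank 0 is column-mean imputation (zero on the centered scale).
svd_complete <- function(Z, rank, maxit = 200, tol = 1e-6) {
  miss <- is.na(Z)
  X <- Z
  mu <- colMeans(Z, na.rm = TRUE)
  X[miss] <- rep(mu, each = nrow(Z))[miss]
  if (rank == 0L) {
    return(X)
  }
  prev <- X[miss]
  for (it in seq_len(maxit)) {
    ctr <- colMeans(X)
    Xc <- sweep(X, 2, ctr)
    sv <- svd(Xc, nu = rank, nv = rank)
    rec <- sweep(
      sv$u %*% diag(sv$d[seq_len(rank)], rank) %*% t(sv$v), 2, ctr, `+`
    )
    X[miss] <- rec[miss]
    if (sum((X[miss] - prev)^2) < tol * max(sum(prev^2), 1e-12)) break
    prev <- X[miss]
  }
  X
}
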