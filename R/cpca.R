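#' Fit a consensus (multi-block) PCA model
#'
#' Consensus PCA (CPCA) extracts components jointly from several row-aligned
#' blocks (here: one block per cultivation medium). Each block is
#' column-centered and scaled to unit Frobenius norm so every medium enters
#' with equal total variance. Components are found by the iterative scheme
#'
#'   p_b = X_b' t / (t' t), normalized;  t_b = X_b p_b;
#'   w = T' t, normalized;  t = T w,  with T = \[t_1 ... t_B\]
#'
#' started from the concatenated column of maximal variance and iterated to a
#' relative score change below `tol`. Every block is then deflated by
#' regression on the global score t (super-score deflation), which makes the
#' global scores of this variant identical, up to per-component sign, to the
#' ordinary PCA scores of the column-concatenated scaled blocks - a property
#' the test suite checks against a direct SVD. Per component the model keeps
#' the global score, per-block scores and unit-norm loadings, the unit-norm
#' super weights w (the contribution of each block to the consensus
#' direction), and global and per-block explained-variance fractions.
#'
#' The sign of each component is fixed by flipping the global score so its
#' largest-magnitude entry is positive, making the output deterministic.
#'
#' @param x A `multiblock_data` from [assemble_blocks()].
#' @param n_components Number of components (at most rows - 1 and the total
#'   column count; fewer are returned, with a warning, if the data have lower
#'   rank).
#' @param tol Relative score-change convergence tolerance.
#' @param max_iter Maximum iterations per component; exceeding it is an error
#'   naming the component.
#' @return An object of class `cpca_model`.
#' @export
fit_cpca <- function(x, n_components = 2, tol = 1e-10, max_iter = 500) {
  stopifnot(inherits(x, "multiblock_data"))
  n <- nrow(x$keys)
  if (n < 2) stop("need at least 2 keys to fit a CPCA model")
  B <- length(x$blocks)
  media <- x$media
  means <- lapply(x$blocks, colMeans)
  centered <- purrr::map2(x$blocks, means, function(m, mu) sweep(m, 2, mu))
  scale_b <- vapply(centered, function(m) sqrt(sum(m^2)), numeric(1))
  if (any(scale_b == 0)) {
    stop("block(s) with zero variance: ",
         paste(media[scale_b == 0], collapse = ", "))
  }
  Xb <- purrr::map2(centered, scale_b, function(m, s) m / s)
  X0 <- Xb # pristine scaled blocks, kept for the projection weights
  p_cols <- vapply(Xb, ncol, integer(1))
  max_comp <- min(n - 1, sum(p_cols))
  if (n_components > max_comp) {
    stop("n_components = ", n_components, " exceeds min(rows - 1, columns) = ",
         max_comp)
  }
  ss_block <- vapply(Xb, function(m) sum(m^2), numeric(1)) # = 1 by scaling
  ss_total <- sum(ss_block)

  K <- n_components
  Tt <- matrix(0, n, K)
  P <- lapply(p_cols, function(p) matrix(0, p, 0))
  Q <- lapply(p_cols, function(p) matrix(0, p, 0))
  Tb <- lapply(seq_len(B), function(b) matrix(0, n, 0))
  W <- matrix(0, B, K, dimnames = list(media, NULL))
  ev_global <- numeric(0)
  ev_block <- matrix(0, B, 0, dimnames = list(media, NULL))
  k_done <- 0L
  for (k in seq_len(K)) {
    Xcat <- do.call(cbind, Xb)
    css <- colSums(Xcat^2)
    if (max(css) < 1e-14 * ss_total) {
      warning("rank-deficient input: returning ", k_done,
              " of the requested ", K, " components")
      break
    }
    t <- Xcat[, which.max(css)]
    # one sweep of the block equations: p_b ~ X_b't, t_b = X_b p_b,
    # w ~ T't, t <- Tw (scale-invariant in t)
    sweep_map <- function(v) {
      a <- lapply(Xb, function(m) crossprod(m, v))
      an <- vapply(a, function(z) sqrt(sum(z^2)), numeric(1))
      if (all(an < 1e-14)) return(NULL)
      pb <- purrr::map2(a, an, function(z, nb) z / nb)
      Tm <- vapply(purrr::map2(Xb, pb, function(m, p) as.vector(m %*% p)),
                   identity, numeric(n))
      w <- crossprod(Tm, v)
      as.vector(Tm %*% (w / sqrt(sum(w^2))))
    }
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      t1 <- sweep_map(t)
      if (is.null(t1)) break
      # the sweep map is odd; orient towards the previous iterate (the
      # reported sign is fixed deterministically after convergence)
      if (sum(t1 * t) < 0) t1 <- -t1
      if (sqrt(sum((t1 - t)^2)) < tol * sqrt(sum(t1^2))) {
        t <- t1
        converged <- TRUE
        break
      }
      t <- t1
      # the sweep is a power iteration on the concatenated cross-product and
      # stalls when the leading singular values are close; restart from the
      # Lanczos dominant direction, which shares the fixed point
      if (it == 30L) {
        t_restart <- sweep_map(lanczos_dominant(Xb, t))
        if (!is.null(t_restart)) t <- t_restart
      }
    }
    if (!converged) {
      stop("CPCA did not converge for component ", k, " within ", max_iter,
           " iterations")
    }
    # deterministic sign: largest-magnitude global score entry positive
    if (t[which.max(abs(t))] < 0) t <- -t
    a <- lapply(Xb, function(m) crossprod(m, t))
    an <- vapply(a, function(v) sqrt(sum(v^2)), numeric(1))
    pb <- purrr::map2(a, an, function(v, nb) v / nb)
    tb <- purrr::map2(Xb, pb, function(m, p) as.vector(m %*% p))
    Tm <- vapply(tb, identity, numeric(n))
    w <- crossprod(Tm, t)
    w <- as.vector(w / sqrt(sum(w^2)))
    tt <- sum(t^2)
    qb <- lapply(Xb, function(m) crossprod(m, t) / tt)
    Xb <- purrr::map2(Xb, qb, function(m, q) m - t %*% t(q))
    removed_b <- tt * vapply(qb, function(q) sum(q^2), numeric(1))
    k_done <- k
    Tt[, k] <- t
    W[, k] <- w
    for (b in seq_len(B)) {
      P[[b]] <- cbind(P[[b]], pb[[b]])
      Q[[b]] <- cbind(Q[[b]], qb[[b]])
      Tb[[b]] <- cbind(Tb[[b]], tb[[b]])
    }
    ev_global <- c(ev_global, sum(removed_b) / ss_total)
    ev_block <- cbind(ev_block, removed_b / ss_block)
  }
  K <- k_done
  Tt <- Tt[, seq_len(K), drop = FALSE]
  W <- W[, seq_len(K), drop = FALSE]
  comp_names <- paste0("PC", seq_len(K))
  colnames(Tt) <- comp_names
  colnames(W) <- comp_names
  rn <- paste(x$keys$strain_id, x$keys$temperature_c, sep = "__")
  rownames(Tt) <- rn
  names(P) <- media; names(Q) <- media; names(Tb) <- media
  for (b in seq_len(B)) {
    colnames(P[[b]]) <- comp_names
    colnames(Q[[b]]) <- comp_names
    colnames(Tb[[b]]) <- comp_names
    rownames(Tb[[b]]) <- rn
  }
  proj <- projection_weights(X0, P, Q, Tt)
  names(proj) <- media
  structure(list(
    n_components = K,
    media = media,
    region = x$region,
    grid = x$grid,
    keys = x$keys,
    block_means = means,
    block_scale = stats::setNames(scale_b, media),
    global_scores = Tt,
    block_scores = Tb,
    block_loadings = P,
    deflation_loadings = Q,
    proj_weights = proj,
    super_weights = W,
    explained_variance = tibble::tibble(
      component = rep(seq_len(K), times = B + 1),
      block = rep(c("global", media), each = K),
      fraction = c(ev_global, as.vector(t(ev_block[, seq_len(K), drop = FALSE])))
    )
  ), class = "cpca_model")
}

# Dominant eigendirection of sum_b X_b X_b' by restarted Lanczos with full
# reorthogonalization: used to re-seed the consensus sweep when the leading
# singular values are too close for power iteration to reach tolerance.
lanczos_dominant <- function(Xb, v0, dim = 30L, restarts = 20L,
                             rtol = 1e-13) {
  Xcat <- do.call(cbind, Xb)
  n <- nrow(Xcat)
  matvec <- function(v) as.vector(Xcat %*% crossprod(Xcat, v))
  v <- v0 / sqrt(sum(v0^2))
  m <- min(dim, n)
  for (r in seq_len(restarts)) {
    V <- matrix(0, n, m)
    V[, 1] <- v
    j_used <- 1L
    for (j in seq_len(m - 1L)) {
      w <- matvec(V[, j])
      for (pass in 1:2) w <- w - V[, 1:j, drop = FALSE] %*%
          crossprod(V[, 1:j, drop = FALSE], w)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      V[, j + 1L] <- w / nw
      j_used <- j + 1L
    }
    V <- V[, seq_len(j_used), drop = FALSE]
    H <- crossprod(V, vapply(seq_len(ncol(V)),
                             function(j) matvec(V[, j]), numeric(n)))
    H <- (H + t(H)) / 2
    e <- eigen(H, symmetric = TRUE)
    v_new <- as.vector(V %*% e$vectors[, 1])
    theta <- e$values[1]
    resid <- sqrt(sum((matvec(v_new) - theta * v_new)^2))
    v <- v_new / sqrt(sum(v_new^2))
    if (resid <= rtol * abs(theta)) break
  }
  v
}

# Linear weights mapping a centered, scaled block row to its sequential block
# scores. The global score of component j is estimated from the block alone
# through the minimum-norm regression rho_j (exact for training rows whenever
# the block spans the centered sample space, i.e. columns >= rows - 1, the
# usual spectral case), and the fitting deflation X <- X - t q' is replayed
# symbolically: r_k = p_k - sum_{j<k} (q_j . p_k) rho_j.
projection_weights <- function(X0, P, Q, Tt) {
  K <- ncol(Tt)
  purrr::pmap(list(X0, P, Q), function(X, Pb, Qb) {
    sv <- svd(X)
    pos <- sv$d > max(sv$d[1], 1e-300) * 1e-12
    rho <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], Tt)) / sv$d[pos])
    R <- matrix(0, nrow(Pb), K, dimnames = dimnames(Pb))
    for (k in seq_len(K)) {
      r <- Pb[, k]
      if (k > 1) {
        j <- seq_len(k - 1)
        cj <- as.vector(crossprod(Qb[, j, drop = FALSE], Pb[, k]))
        r <- r - rho[, j, drop = FALSE] %*% cj
      }
      R[, k] <- r
    }
    R
  })
}

#' Project spectra onto one block's score space
#'
#' Scores new (or training) spectra against the loadings of a single block -
#' e.g. project every replicate of every sample onto the BHI block of a
#' fitted model so isolates that never grew on minimal media still appear in
#' the score space. Inputs are centered with the block's stored column means,
#' scaled by its stored block scale, and scored sequentially against the
#' block's per-component loadings with the fitting deflation replayed;
#' projecting the block's own training rows reproduces the stored block
#' scores, and projecting the stored column-mean vector gives zero scores.
#'
#' @param model A `cpca_model`.
#' @param medium Which block to project onto (e.g. `"BHI"`).
#' @param x A `spectra_set` on the model's region grid (preprocessed the same
#'   way as the training data; replicate-level or averaged).
#' @return A tibble: sample metadata plus one `PC<k>` column per component.
#' @export
project_block <- function(model, medium, x) {
  stopifnot(inherits(model, "cpca_model"), inherits(x, "spectra_set"))
  if (!medium %in% model$media) {
    stop("unknown medium '", medium, "'; model blocks: ",
         paste(model$media, collapse = ", "))
  }
  if (length(x$grid) != length(model$grid) ||
      max(abs(x$grid - model$grid)) > 1e-9) {
    stop("input grid does not match the model's region grid")
  }
  Xc <- sweep(x$values, 2, model$block_means[[medium]]) /
    model$block_scale[[medium]]
  scores <- Xc %*% model$proj_weights[[medium]]
  dplyr::bind_cols(x$meta, tibble::as_tibble(scores))
}

#' Explained-variance table of a CPCA model
#'
#' Global and per-block explained-variance fractions per component, one row
#' per component with a `global` column and one column per medium block.
#'
#' @param model A `cpca_model`.
#' @return A wide tibble (`component`, `global`, one column per block).
#' @export
explained_variance_report <- function(model) {
  stopifnot(inherits(model, "cpca_model"))
  tidyr::pivot_wider(model$explained_variance,
                     names_from = "block", values_from = "fraction")
}

#' @export
print.cpca_model <- function(x, ...) {
  cat("<cpca_model> ", x$n_components, " components, ", nrow(x$keys),
      " keys, ", length(x$media), " blocks (",
      paste(x$media, collapse = ", "), ")",
      if (!is.null(x$region)) paste0(", region: ", x$region), "\n", sep = "")
  ev <- x$explained_variance
  g <- ev$fraction[ev$block == "global"]
  cat("  global explained variance:",
      paste(sprintf("%.1f%%", 100 * g), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy components of a CPCA model
#'
#' @param x A `cpca_model`.
#' @param matrix Which artifact to return: `"scores"` (global scores joined to
#'   the sample keys), `"block_scores"`, `"loadings"` (per-block unit
#'   loadings, long over wavenumbers), `"weights"` (super weights), or
#'   `"variance"` (long explained-variance fractions).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cpca_model
#' @export
tidy.cpca_model <- function(x, matrix = c("scores", "block_scores",
                                          "loadings", "weights",
                                          "variance"), ...) {
  matrix <- match.arg(matrix)
  comp_cols <- colnames(x$global_scores)
  switch(matrix,
    scores = dplyr::bind_cols(x$keys, tibble::as_tibble(x$global_scores)),
    block_scores = purrr::imap(x$block_scores, function(m, med) {
      dplyr::bind_cols(x$keys, medium = med, tibble::as_tibble(m))
    }) |> purrr::list_rbind(),
    loadings = purrr::imap(x$block_loadings, function(m, med) {
      tibble::tibble(medium = med,
                     wavenumber_cm1 = rep(x$grid, times = ncol(m)),
                     component = rep(seq_len(ncol(m)), each = nrow(m)),
                     loading = as.vector(m))
    }) |> purrr::list_rbind(),
    weights = tibble::tibble(
      medium = rep(rownames(x$super_weights), times = ncol(x$super_weights)),
      component = rep(seq_along(comp_cols), each = nrow(x$super_weights)),
      weight = as.vector(x$super_weights)
    ),
    variance = x$explained_variance
  )
}

#' One-row summary of a CPCA model
#' @param x A `cpca_model`.
#' @param ... Unused.
#' @return A tibble with component/key/block counts and cumulative global
#'   explained variance.
#' @method glance cpca_model
#' @export
glance.cpca_model <- function(x, ...) {
  ev <- x$explained_variance
  tibble::tibble(
    n_components = x$n_components,
    n_keys = nrow(x$keys),
    n_blocks = length(x$media),
    cum_global_variance = sum(ev$fraction[ev$block == "global"])
  )
}

#' Score and super-weight plots for a CPCA model
#'
#' @param object A `cpca_model`.
#' @param type `"scores"` for the global score scatter (coloured by genus,
#'   labelled by temperature) or `"weights"` for the per-block super weights.
#' @param components Two component indices to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cpca_model
#' @export
autoplot.cpca_model <- function(object, type = c("scores", "weights"),
                                components = c(1, 2), ...) {
  type <- match.arg(type)
  ev <- object$explained_variance
  pct <- function(k) {
    sprintf("PC%d (%.1f%%)", k,
            100 * ev$fraction[ev$block == "global" & ev$component == k])
  }
  cx <- paste0("PC", components[1]); cy <- paste0("PC", components[2])
  if (type == "scores") {
    d <- tidy.cpca_model(object, "scores")
    ggplot2::ggplot(d, ggplot2::aes(x = .data[[cx]], y = .data[[cy]],
                                    colour = .data$genus)) +
      ggplot2::geom_text(ggplot2::aes(label = .data$temperature_c),
                         size = 3) +
      ggplot2::labs(x = pct(components[1]), y = pct(components[2]),
                    title = paste("Global scores -", object$region, "region")) +
      ggplot2::theme_minimal()
  } else {
    w <- tibble::tibble(medium = rownames(object$super_weights),
                        wx = object$super_weights[, components[1]],
                        wy = object$super_weights[, components[2]])
    ggplot2::ggplot(w, ggplot2::aes(x = .data$wx, y = .data$wy,
                                    label = .data$medium)) +
      ggplot2::geom_point() +
      ggplot2::geom_text(vjust = -0.6) +
      ggplot2::labs(x = pct(components[1]), y = pct(components[2]),
                    title = "Super weights (block contributions)") +
      ggplot2::theme_minimal()
  }
}

#' Leave-one-strain-out genus recovery from CPCA global scores
#'
#' Nearest-centroid classification of genus in the space of the first
#' `n_components` global scores: for each strain in turn, genus centroids are
#' computed from all other strains' score rows and every held-out row is
#' assigned to the nearest centroid. Measures how well the consensus
#' components separate genera without reusing the evaluated strain.
#'
#' @param model A `cpca_model` whose keys carry `genus` and `strain_id`.
#' @param n_components Number of leading components to use (default 3, capped
#'   at the model's component count).
#' @return A list: `accuracy` (fraction correct), `n` (rows classified), and
#'   `predictions` (tibble with `strain_id`, `temperature_c`, `genus`,
#'   `predicted`).
#' @export
genus_recovery_accuracy <- function(model, n_components = 3) {
  stopifnot(inherits(model, "cpca_model"))
  K <- min(n_components, model$n_components)
  S <- model$global_scores[, seq_len(K), drop = FALSE]
  keys <- model$keys
  pred <- character(nrow(keys))
  for (s in unique(keys$strain_id)) {
    hold <- keys$strain_id == s
    train <- S[!hold, , drop = FALSE]
    centroids <- rowsum(train, keys$genus[!hold]) /
      as.vector(table(keys$genus[!hold]))
    d2 <- outer(rowSums(S[hold, , drop = FALSE]^2),
                rowSums(centroids^2), "+") -
      2 * S[hold, , drop = FALSE] %*% t(centroids)
    pred[hold] <- rownames(centroids)[apply(d2, 1, which.min)]
  }
  list(
    accuracy = mean(pred == keys$genus),
    n = nrow(keys),
    predictions = dplyr::bind_cols(
      keys[, c("strain_id", "temperature_c", "genus")],
      tibble::tibble(predicted = pred))
  )
}
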