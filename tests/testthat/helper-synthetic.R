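# Shared fixture builders: everything is generated in code at test time.

make_meta <- function(n, medium = "BHI", temperature_c = 18L,
                      strain_id = paste0("S", seq_len(n)),
                      genus = "Arthrobacter") {
  tibble::tibble(
    sample_id = paste0("s", seq_len(n)),
    strain_id = strain_id,
    genus = genus,
    species = paste(genus, "sp."),
    medium = medium,
    temperature_c = temperature_c,
    bio_rep = 1L,
    tech_rep = 1L
  )
}

# spectra_set built from functions of the wavenumber
fun_set <- function(funs, grid = seq(500, 4000, by = 2), ...) {
  vals <- t(vapply(funs, function(f) f(grid), numeric(length(grid))))
  spectra_set(vals, grid, make_meta(length(funs), ...))
}

gauss <- function(center, sigma, height = 1) {
  force(center); force(sigma); force(height)
  function(nu) height * exp(-(nu - center)^2 / (2 * sigma^2))
}

# small default-shaped study: 2 genera x 2 strains, full design
small_config <- function(...) {
  synthetic_config(genera = c("Arthrobacter", "Pseudomonas"),
                   n_strains_per_genus = 2, ...)
}

# single genus grown on BHI only (minimal-media bands set to "0")
bhi_only_config <- function(genus = "Cryobacterium", n_strains = 5, ...) {
  des <- default_growth_design(genus, ftir_media, ftir_temperatures)
  des$band[des$medium != "BHI"] <- "0"
  synthetic_config(genera = genus, n_strains_per_genus = n_strains,
                   growth_design = des, ...)
}

# multiblock_data wrapper around bare matrices (for oracle tests)
make_mb <- function(blocks, media = paste0("B", seq_along(blocks))) {
  n <- nrow(blocks[[1]])
  blocks <- stats::setNames(blocks, media)
  structure(list(
    keys = tibble::tibble(strain_id = paste0("S", seq_len(n)),
                          temperature_c = 18L,
                          genus = "Arthrobacter", species = "sp."),
    blocks = blocks,
    grid = seq_len(ncol(blocks[[1]])),
    media = media,
    region = NULL,
    dropped = tibble::tibble(strain_id = character(),
                             temperature_c = integer())
  ), class = "multiblock_data")
}

# SVD oracle for super-score-deflation CPCA: PCA of the column-concatenated,
# per-block centered and Frobenius-scaled matrix.
cpca_svd_oracle <- function(blocks, n_components) {
  scaled <- lapply(blocks, function(m) {
    mc <- sweep(m, 2, colMeans(m))
    mc / sqrt(sum(mc^2))
  })
  X <- do.call(cbind, scaled)
  sv <- svd(X)
  scores <- sv$u[, seq_len(n_components), drop = FALSE] %*%
    diag(sv$d[seq_len(n_components)], n_components)
  list(scores = scores, ev = sv$d^2 / sum(sv$d^2))
}

# align oracle columns to fitted signs before comparing
align_signs <- function(target, ref) {
  for (k in seq_len(ncol(target))) {
    if (sum(target[, k] * ref[, k]) < 0) target[, k] <- -target[, k]
  }
  target
}

subset_ss <- function(x, idx) {
  spectra_set(x$values[idx, , drop = FALSE], x$grid, x$meta[idx, , drop = FALSE])
}
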