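# Synthetic Visium-like fixtures: spot lattices, spatially smooth
# embeddings with controllable noise, domain labels, and benchmark suites
# with a known quality ordering. Everything is deterministic given a seed.

#' Generate a spot lattice
#'
#' `"square"` is the integer grid; `"hex"` offsets every other row by half
#' a spacing in x and packs rows at `sqrt(3)/2` (the Visium arrangement),
#' so the nearest-neighbour spacing is 1 in both cases.
#'
#' @param rows,cols Lattice dimensions (`rows * cols >= 4` spots).
#' @param lattice `"hex"` (default) or `"square"`.
#' @return Coordinates tibble (`spot`, `x`, `y`), spots in row-major order.
#' @examples
#' make_lattice(2, 2, "square")
#' @export
make_lattice <- function(rows, cols, lattice = c("hex", "square")) {
  lattice <- match.arg(lattice)
  rows <- check_count(rows, "rows", min = 1L)
  cols <- check_count(cols, "cols", min = 1L)
  if (rows * cols < 4L) abort("lattice needs at least 4 spots.")
  r <- rep(seq_len(rows) - 1L, each = cols)
  c_ <- rep(seq_len(cols) - 1L, times = rows)
  if (lattice == "square") {
    x <- as.numeric(c_)
    y <- as.numeric(r)
  } else {
    x <- c_ + 0.5 * (r %% 2L)
    y <- r * sqrt(3) / 2
  }
  tibble(spot = sprintf("s%04d", seq_along(x)), x = x, y = y)
}

#' Partition a lattice into contiguous domains
#'
#' Splits the spots into `n_domains` bands of (near-)equal size along the
#' x axis — a stand-in for annotated tissue layers.
#'
#' @param coords Coordinates tibble.
#' @param n_domains Number of domains (>= 2).
#' @return Labels tibble (`spot`, `label`), labels `domain_1..domain_k`.
#' @export
make_labels <- function(coords, n_domains = 4L) {
  n_domains <- check_count(n_domains, "n_domains", min = 2L)
  xy <- coordinate_matrix(coords)
  if (n_domains > nrow(xy)) abort("more domains than spots.")
  ord <- order(xy[, "x"], xy[, "y"])
  band <- integer(nrow(xy))
  band[ord] <- ceiling(seq_along(ord) / (length(ord) / n_domains))
  tibble(spot = rownames(xy), label = sprintf("domain_%d", pmin(band, n_domains)))
}

#' Generate a synthetic embedding with controlled spatial smoothness
#'
#' Each dimension is an independent spatial field plus i.i.d. Gaussian
#' noise. The field starts from a per-domain Gaussian level (so clustering
#' structure matches [make_labels()]) perturbed spot-wise, is smoothed with
#' a Gaussian kernel of length-scale `smoothness` (in units of the lattice
#' spacing) over the coordinates, and is standardised to unit variance.
#' `smoothness = 0` drops the field entirely, leaving pure noise; larger
#' `noise_sd` buries the spatial signal and drives Moran's I towards its
#' null value `-1/(n-1)`.
#'
#' @param coords Coordinates tibble.
#' @param n_dims Number of embedding dimensions. Default 3.
#' @param smoothness Kernel length-scale (>= 0) of the spatial field.
#' @param noise_sd Standard deviation (>= 0) of the additive noise, on the
#'   unit-variance scale of the field.
#' @param n_domains Domains used for the field's block structure.
#' @param seed Integer seed; the output is reproducible given
#'   (`coords`, arguments, `seed`).
#' @return Embedding tibble (`spot`, `dim1..dimD`).
#' @export
make_embedding <- function(coords, n_dims = 3L, smoothness = 2,
                           noise_sd = 0.5, n_domains = 4L, seed = 1L) {
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (smoothness == 0 && noise_sd == 0) {
    abort("smoothness = 0 with noise_sd = 0 would produce a constant embedding.")
  }
  field <- make_field(coords, n_dims, smoothness, n_domains, seed)
  add_noise(field, noise_sd, seed = as.integer(seed) + 1L)
}

# Unit-variance smooth spatial field per dimension (zero if smoothness = 0).
make_field <- function(coords, n_dims = 3L, smoothness = 2, n_domains = 4L,
                       seed = 1L) {
  n_dims <- check_count(n_dims, "n_dims", min = 1L)
  if (!is.numeric(smoothness) || smoothness < 0) {
    abort("`smoothness` must be >= 0.")
  }
  xy <- coordinate_matrix(coords)
  n <- nrow(xy)
  mat <- matrix(0, n, n_dims)
  if (smoothness > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    D2 <- as.matrix(dist(xy))^2
    K <- exp(-D2 / (2 * smoothness^2))
    K <- K / rowSums(K)
    domains <- make_labels(coords, n_domains)$label
    for (d in seq_len(n_dims)) {
      level <- rnorm(n_domains)
      raw <- level[match(domains, sprintf("domain_%d", seq_len(n_domains)))] +
        rnorm(n)
      field <- as.numeric(K %*% raw)
      s <- sd(field)
      if (s > 0) field <- field / s
      mat[, d] <- field
    }
  }
  rownames(mat) <- rownames(xy)
  colnames(mat) <- paste0("dim", seq_len(n_dims))
  as_embedding_tibble(mat)
}

add_noise <- function(field, noise_sd, seed) {
  mat <- embedding_matrix(field)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  mat <- mat + noise_sd * matrix(rnorm(length(mat)), nrow(mat), ncol(mat))
  as_embedding_tibble(mat, ids = field$spot)
}

#' Generate a benchmark suite of embeddings with a known quality order
#'
#' Produces `m` embeddings on the same lattice, named `e01..e<m>`. All
#' suite members share one underlying smooth field (drawn once from
#' `seed`) and differ only in the standard deviation of their additive
#' noise, stepped geometrically from `noise_range[1]` (worst) down to
#' `noise_range[2]` (best) — mimicking one tissue represented at varying
#' fidelity by different hyperparameter settings. Sharing the field is what
#' makes the construction order a genuine quality order: with independent
#' fields the comparison would be dominated by field-to-field luck instead
#' of noise level. The construction-truth ranking (rank 1 = lowest noise)
#' and a domain label table accompany the embeddings, so both score-based
#' and ARI-based rankings can be validated against a known ordering.
#'
#' @param coords Coordinates tibble.
#' @param m Number of embeddings (>= 2). Default 8.
#' @param n_dims,smoothness,n_domains Passed to [make_embedding()].
#' @param noise_range Length-2 numeric, noise sd of the worst and best
#'   embedding. Default `c(4, 0.05)`.
#' @param seed Integer seed; embedding `i` uses `seed + i`.
#' @return List with elements `embeddings` (named list of tibbles),
#'   `truth` (tibble `name`, `noise_sd`, `rank` with rank 1 = best) and
#'   `labels` (tibble `spot`, `label`).
#' @examples
#' suite <- make_suite(make_lattice(6, 6), m = 3, seed = 7)
#' suite$truth
#' @export
make_suite <- function(coords, m = 8L, n_dims = 3L, smoothness = 2,
                       n_domains = 4L, noise_range = c(4, 0.05),
                       seed = 1L) {
  m <- check_count(m, "m", min = 2L)
  if (length(noise_range) != 2L || any(noise_range <= 0) ||
      noise_range[1] <= noise_range[2]) {
    abort("`noise_range` must be two positive values, high then low.")
  }
  noise <- exp(seq(log(noise_range[1]), log(noise_range[2]), length.out = m))
  names_ <- sprintf("e%02d", seq_len(m))
  field <- make_field(coords, n_dims = n_dims, smoothness = smoothness,
                      n_domains = n_domains, seed = seed)
  embeddings <- purrr::map(seq_len(m), function(i) {
    add_noise(field, noise[i], seed = as.integer(seed) + i)
  })
  names(embeddings) <- names_
  truth <- tibble(name = names_, noise_sd = noise, rank = rev(seq_len(m)))
  list(embeddings = embeddings,
       truth = truth[order(truth$rank), , drop = FALSE],
       labels = make_labels(coords, n_domains))
}
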