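#' Specification for one synthetic water cluster
#'
#' Describes a non-equilibrium (H2O)n configuration: oxygens placed by
#' rejection sampling inside a cubic box with a minimum O-O separation,
#' each monomer built at the reference internal geometry, randomly oriented,
#' then distorted by Gaussian perturbations of the two O-H lengths and the
#' H-O-H angle. The box side controls compactness: small boxes give
#' compressed clusters (small radius of gyration), large boxes extended
#' ones.
#'
#' @param n_monomers Number of water molecules.
#' @param box_side Cube edge, Angstrom (default scales as `n^(1/3)` at a
#'   roughly liquid-like O density, loosened 25%).
#' @param min_oo Minimum O-O distance, Angstrom.
#' @param distort_sigma_r Gaussian sigma of the O-H length distortion, A.
#' @param distort_sigma_theta Gaussian sigma of the angle distortion, deg.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @param id Structure id (default derived from size and seed).
#' @return A list of class `cluster_spec`.
#' @export
cluster_spec <- function(n_monomers, box_side = NULL, min_oo = 2.5,
                         distort_sigma_r = 0.02, distort_sigma_theta = 2,
                         seed = 1L, id = NULL) {
  if (n_monomers < 1L)
    d4_abort("n_monomers must be at least 1", "d4tune_domain_error")
  if (min_oo <= 0) d4_abort("min_oo must be positive", "d4tune_domain_error")
  if (is.null(box_side)) box_side <- 1.25 * 3.1 * n_monomers^(1 / 3)
  if (is.null(id)) id <- sprintf("w%d_s%d", n_monomers, seed)
  structure(list(n_monomers = as.integer(n_monomers), box_side = box_side,
                 min_oo = min_oo, distort_sigma_r = distort_sigma_r,
                 distort_sigma_theta = distort_sigma_theta,
                 seed = as.integer(seed), id = id),
            class = "cluster_spec")
}

# uniform random rotation matrix (QR of a Gaussian matrix, det fixed to +1)
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate one synthetic water cluster
#'
#' Deterministic for a fixed spec (seed included). Atom order is O, H, H per
#' monomer. With zero distortion sigmas every monomer sits exactly at the
#' reference internal geometry.
#'
#' @param spec A [cluster_spec()].
#' @param ref Reference internal geometry of the monomer.
#' @return An [xyz_structure()].
#' @export
gen_cluster <- function(spec, ref = ref_geometry()) {
  withr::with_seed(spec$seed, {
    n <- spec$n_monomers
    centers <- matrix(NA_real_, n, 3)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 5000L * n
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        d4_abort(sprintf(
          "could not place %d oxygens with min O-O %.2f A in a %.2f A box; try a larger box",
          n, spec$min_oo, spec$box_side), "d4tune_generation_error")
      p <- stats::runif(3, 0, spec$box_side)
      if (placed == 0L ||
          min(sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE],
                                 2L, p)^2))) >= spec$min_oo) {
        placed <- placed + 1L
        centers[placed, ] <- p
      }
    }
    elements <- character(0)
    xyz <- matrix(0, 0, 3)
    for (k in seq_len(n)) {
      r1 <- ref$r_oh + stats::rnorm(1, 0, spec$distort_sigma_r)
      r2 <- ref$r_oh + stats::rnorm(1, 0, spec$distort_sigma_r)
      th <- (ref$theta_hoh +
               stats::rnorm(1, 0, spec$distort_sigma_theta)) * pi / 180
      local <- rbind(c(0, 0, 0),
                     c(r1, 0, 0),
                     c(r2 * cos(th), r2 * sin(th), 0))
      rot <- .random_rotation()
      pos <- local %*% t(rot)
      pos <- sweep(pos, 2L, centers[k, ], `+`)
      elements <- c(elements, c("O", "H", "H"))
      xyz <- rbind(xyz, pos)
    }
    xyz_structure(elements, xyz, id = spec$id,
                  comment = sprintf("id=%s n=%d seed=%d", spec$id, n, spec$seed))
  })
}

#' Ladder of cluster specs across growing sizes
#'
#' For each requested size, `n_per_size` specs whose box sides sweep a
#' compact-to-extended range, so every size yields an ensemble spanning
#' compressed and loose configurations; mean radius of gyration grows
#' strictly with the cluster size. Seeds are distinct across specs.
#'
#' @param sizes Cluster sizes (numbers of monomers).
#' @param n_per_size Configurations per size.
#' @param seed Base seed; spec seeds derive from it.
#' @param distort_sigma_r,distort_sigma_theta Monomer distortion sigmas.
#' @param min_oo Minimum O-O distance, Angstrom.
#' @return List of [cluster_spec()] objects, length
#'   `length(sizes) * n_per_size`.
#' @export
ladder_specs <- function(sizes = c(6, 9, 15, 27), n_per_size = 25L, seed = 1L,
                         distort_sigma_r = 0.02, distort_sigma_theta = 2,
                         min_oo = 2.5) {
  if (!length(sizes))
    d4_abort("sizes must be non-empty", "d4tune_domain_error")
  factors <- if (n_per_size == 1L) 1.3 else
    seq(1.1, 1.7, length.out = n_per_size)
  specs <- list()
  k <- 0L
  for (n in sizes) for (j in seq_len(n_per_size)) {
    k <- k + 1L
    specs[[k]] <- cluster_spec(
      n, box_side = factors[j] * 3.1 * n^(1 / 3), min_oo = min_oo,
      distort_sigma_r = distort_sigma_r,
      distort_sigma_theta = distort_sigma_theta,
      seed = seed + 131L * k,
      id = sprintf("w%02d_c%03d", n, k))
  }
  specs
}

#' Specification of a mock energy table
#'
#' Ground truth for the synthetic pipeline: the benchmark-minus-method gap
#' of every cluster is, by construction, `s6_true e6_raw + s8_true e8_raw`
#' plus Gaussian noise. The default noise scale is 0.1 kcal/mol per monomer
#' (the statistical error scale typical of stochastic benchmark methods);
#' `noise_sigma` overrides it with a flat per-cluster value.
#'
#' @param s6_true,s8_true Ground-truth scaling factors.
#' @param noise_per_monomer Per-monomer noise sigma, kcal/mol.
#' @param noise_sigma Optional flat per-cluster sigma overriding the
#'   per-monomer rule.
#' @param seed Integer seed for the noise stream.
#' @return A list of class `mock_energy_spec`.
#' @export
mock_energy_spec <- function(s6_true = 1, s8_true = 2, noise_per_monomer = 0.1,
                             noise_sigma = NULL, seed = 1L) {
  if (!is.null(noise_sigma) && noise_sigma < 0)
    d4_abort("noise_sigma must be non-negative", "d4tune_domain_error")
  structure(list(s6_true = s6_true, s8_true = s8_true,
                 noise_per_monomer = noise_per_monomer,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "mock_energy_spec")
}

# Additive pairwise mock interaction over O-O pairs: a Lennard-Jones-like
# term plus a short-range Gaussian attraction standing in for hydrogen
# bonding. Its exact form cancels in the deviation construction; it only
# sets realistic magnitudes (tens of kcal/mol per cluster).
mock_base_energy <- function(s, partition) {
  io <- vapply(partition, `[[`, 0L, 1L)
  if (length(io) < 2L) return(0)
  xyz <- s$xyz[io, , drop = FALSE]
  pr <- which(upper.tri(matrix(0, length(io), length(io))), arr.ind = TRUE)
  dv <- xyz[pr[, 1L], , drop = FALSE] - xyz[pr[, 2L], , drop = FALSE]
  r <- sqrt(rowSums(dv^2))
  eps <- 0.15; sig <- 3.1
  lj <- eps * ((sig / r)^12 - 2 * (sig / r)^6)
  hb <- -4.5 * exp(-((r - 2.85) / 0.35)^2 / 2)
  sum(lj + hb)
}

#' Generate a complete synthetic dataset
#'
#' Runs the whole pipeline in reverse: generates the cluster geometries,
#' computes their dispersion components under the supplied parameters, and
#' emits mock energy tables in which the benchmark is *exactly* the method
#' energy stabilized by `s6_true e6_raw + s8_true e8_raw` plus noise.
#' Monomer energies (both methods) come from the harmonic backend, so
#' one-body deviations cancel and the assembled pre-dispersion deviation of
#' every cluster equals `s6_true e6 + s8_true e8 + noise` — the identity the
#' refit machinery is tested against.
#'
#' @param specs List of [cluster_spec()] (e.g. from [ladder_specs()]).
#' @param mock A [mock_energy_spec()].
#' @param fp A [functional_params()] object for the component evaluation.
#' @param method,reference_method Labels used in the emitted energy table.
#' @param backend Monomer backend used for the per-monomer energy columns.
#' @return A list: `structures`, `energies` (records as in
#'   [read_energy_table()]), `components` (data.frame), `truth` (data.frame
#'   with per-structure `e6_raw`, `e8_raw`, `base`, `noise`), and the
#'   `mock` spec.
#' @export
gen_dataset <- function(specs, mock, fp, method = "DFT",
                        reference_method = "MC",
                        backend = harmonic_backend()) {
  structures <- lapply(specs, gen_cluster)
  comp <- components_table(structures, fp)
  energies <- vector("list", length(specs))
  truth <- vector("list", length(specs))
  noise <- withr::with_seed(mock$seed, {
    sig <- if (!is.null(mock$noise_sigma)) rep(mock$noise_sigma, length(specs))
           else mock$noise_per_monomer *
             vapply(specs, `[[`, 0L, "n_monomers")
    stats::rnorm(length(specs), 0, sig)
  })
  for (i in seq_along(specs)) {
    s <- structures[[i]]
    part <- partition_monomers(s)
    base <- mock_base_energy(s, part)
    emono <- monomer_energies(s, part, backend)
    edis <- mock$s6_true * comp$e6_raw[i] + mock$s8_true * comp$e8_raw[i]
    e_method <- base + sum(emono)
    e_bench <- e_method - edis - noise[i]
    energies[[i]] <- list(
      structure_id = s$id, n_monomers = length(part),
      e_total = stats::setNames(c(e_method, e_bench),
                                c(method, reference_method)),
      e_ref_monomer = stats::setNames(c(0, 0), c(method, reference_method)),
      e_monomers = stats::setNames(list(emono, emono),
                                   c(method, reference_method)))
    truth[[i]] <- data.frame(structure_id = s$id,
                             n_monomers = length(part),
                             e6_raw = comp$e6_raw[i], e8_raw = comp$e8_raw[i],
                             base = base, noise = noise[i],
                             stringsAsFactors = FALSE)
  }
  list(structures = structures, energies = energies, components = comp,
       truth = do.call(rbind, truth), mock = mock)
}
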