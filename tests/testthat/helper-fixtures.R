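# Shared fixtures, all built in code.

# one water monomer at the reference internal geometry, O at `origin`,
# molecule in the xy plane
ref_monomer_xyz <- function(origin = c(0, 0, 0), r = 0.95865, theta = 104.348) {
  th <- theta * pi / 180
  rbind(c(0, 0, 0),
        c(r, 0, 0),
        c(r * cos(th), r * sin(th), 0)) + rep(origin, each = 3)
}

ref_monomer <- function(origin = c(0, 0, 0), id = "mono") {
  xyz_structure(c("O", "H", "H"), ref_monomer_xyz(origin), id = id)
}

two_monomers <- function(sep = 3.0) {
  xyz_structure(rep(c("O", "H", "H"), 2),
                rbind(ref_monomer_xyz(c(0, 0, 0)),
                      ref_monomer_xyz(c(sep, 0, 0))),
                id = "dimer")
}

# toy dispersion parameters in working units (kcal/mol, Angstrom):
# C6 = 1 for every pair, Q = 1 (so C8 = 3), undamped unless a1/a2 given
toy_fp <- function(a1 = 0, a2 = 0, sr8 = 1, c6 = 1, q = 1,
                   elements = c("H", "O")) {
  c6m <- matrix(c6, length(elements), length(elements),
                dimnames = list(elements, elements))
  list(functional = "toy", s6 = 1, s8 = 1, a1 = a1, a2 = a2, sr8 = sr8,
       q = stats::setNames(rep(q, length(elements)), elements), c6 = c6m)
}

water_fp <- function(functional = "B3LYP") {
  functional_params(read_d4_params(d4_water_params_file()), functional)
}

# random small structure of H/O atoms with all pair distances >= min_r
random_structure <- function(n, min_r = 0.8, id = "rand") {
  repeat {
    xyz <- matrix(stats::runif(3 * n, 0, max(3, n^(1 / 3) * 2.2)), ncol = 3)
    if (n < 2 || min(stats::dist(xyz)) >= min_r) break
  }
  xyz_structure(sample(c("H", "O"), n, replace = TRUE), xyz, id = id)
}

# independent straight-loop dispersion sum at given scaling factors
# (re-summation oracle: no shared code with cluster_components)
direct_dispersion_sum <- function(s, fp, s6, s8) {
  total <- 0
  n <- length(s$elements)
  if (n < 2) return(0)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    r <- sqrt(sum((s$xyz[a, ] - s$xyz[b, ])^2))
    c6 <- fp$c6[s$elements[a], s$elements[b]]
    c8 <- 3 * c6 * sqrt(fp$q[[s$elements[a]]] * fp$q[[s$elements[b]]])
    r0 <- fp$a1 * sqrt(c8 / c6) + fp$a2
    f6 <- r^6 / (r^6 + r0^6)
    f8 <- r^8 / (r^8 + (fp$sr8 * r0)^8)
    total <- total + s6 * c6 * f6 / r^6 + s8 * c8 * f8 / r^8
  }
  total
}

# fitting table with known ground truth: deviation = s6*e6 + s8*e8 + noise
synthetic_fit_records <- function(n, s6_true, s8_true, noise = 0, seed = 1) {
  withr::with_seed(seed, {
    e6 <- stats::runif(n, 0.5, 5)
    e8 <- stats::runif(n, 0.2, 3)
    eps <- if (length(noise) == 1 && noise == 0) rep(0, n)
           else stats::rnorm(n, 0, noise)
    data.frame(structure_id = sprintf("r%03d", seq_len(n)), n_monomers = 9L,
               deviation = s6_true * e6 + s8_true * e8 + eps,
               e6_raw = e6, e8_raw = e8, stringsAsFactors = FALSE)
  })
}
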