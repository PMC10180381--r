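#' Read a dispersion parameter file
#'
#' Parses the key-value parameter format shipped in
#' `inst/extdata/d4_water_params.txt`: per-element multipole ratios
#' (`element <sym> q=<Q>`), symmetric pairwise C6 coefficients
#' (`pair <a> <b> c6=<v>`) and per-functional scaling/damping constants
#' (`functional <name> s6=.. s8=.. a1=.. a2=..`, optional `sr8=`).
#' A `# units:` header of `au` (hartree/bohr, the default) or
#' `kcal_angstrom` declares the units; atomic units are converted to
#' kcal/mol and Angstrom once at load time.
#'
#' @param file Path to a parameter file.
#' @return A list of class `d4_params` with components `q` (named vector,
#'   Angstrom^2), `c6` (symmetric named matrix, kcal mol^-1 A^6) and
#'   `functionals` (named list of `s6`, `s8`, `a1`, `a2` (Angstrom), `sr8`).
#' @export
read_d4_params <- function(file) {
  lines <- readLines(file)
  units <- "au"
  uh <- grep("^#\\s*units\\s*:", lines, value = TRUE)
  if (length(uh)) units <- trimws(sub("^#\\s*units\\s*:", "", uh[1L]))
  if (!units %in% c("au", "kcal_angstrom"))
    d4_abort(sprintf("unknown units declaration '%s' in parameter file", units),
             "d4tune_format_error")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- function(fields, keys) {
    pairs <- strsplit(fields, "=", fixed = TRUE)
    vals <- stats::setNames(
      suppressWarnings(as.numeric(vapply(pairs, `[[`, "", 2L))),
      vapply(pairs, `[[`, "", 1L))
    missing <- setdiff(keys, names(vals))
    if (length(missing) || anyNA(vals[keys]))
      d4_abort(paste0("parameter record missing/invalid key(s): ",
                      paste(missing, collapse = ", ")), "d4tune_format_error")
    vals
  }
  q <- c(); c6_rec <- list(); funs <- list()
  for (ln in lines) {
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    switch(f[1L],
      element = { q[f[2L]] <- kv(f[-(1:2)], "q")[["q"]] },
      pair = {
        v <- kv(f[-(1:3)], "c6")[["c6"]]
        c6_rec[[length(c6_rec) + 1L]] <- list(a = f[2L], b = f[3L], c6 = v)
      },
      functional = {
        v <- kv(f[-(1:2)], c("s6", "s8", "a1", "a2"))
        funs[[f[2L]]] <- list(s6 = v[["s6"]], s8 = v[["s8"]],
                              a1 = v[["a1"]], a2 = v[["a2"]],
                              sr8 = if ("sr8" %in% names(v)) v[["sr8"]] else 1)
      },
      d4_abort(sprintf("unrecognized parameter record '%s'", ln),
               "d4tune_format_error"))
  }
  if (any(q <= 0)) d4_abort("q factors must be positive", "d4tune_domain_error")
  els <- sort(unique(c(names(q), unlist(lapply(c6_rec, function(r) c(r$a, r$b))))))
  c6 <- matrix(NA_real_, length(els), length(els), dimnames = list(els, els))
  for (r in c6_rec) {
    if (r$c6 < 0) d4_abort("C6 coefficients must be non-negative",
                           "d4tune_domain_error")
    c6[r$a, r$b] <- r$c6
    c6[r$b, r$a] <- r$c6
  }
  if (units == "au") {
    hk <- d4_constants$hartree_kcal
    b <- d4_constants$bohr_ang
    c6 <- c6 * hk * b^6      # hartree bohr^6 -> kcal/mol A^6
    q <- q * b^2             # bohr^2 -> A^2 (keeps C8 = 3 C6 sqrt(QaQb) consistent)
    funs <- lapply(funs, function(fn) { fn$a2 <- fn$a2 * b; fn })
  }
  structure(list(q = q, c6 = c6, functionals = funs), class = "d4_params")
}

#' @export
print.d4_params <- function(x, ...) {
  cat(sprintf("<d4_params: elements %s; functionals %s>\n",
              paste(names(x$q), collapse = ","),
              paste(names(x$functionals), collapse = ",")))
  invisible(x)
}

#' Flatten parameters for one functional
#'
#' @param params A `d4_params` object from [read_d4_params()].
#' @param functional Functional name present in the parameter file.
#' @return A list of class `functional_params`: `functional`, default `s6`
#'   and `s8`, damping constants `a1`, `a2`, `sr8`, and the element tables
#'   `q` and `c6`.
#' @export
functional_params <- function(params, functional) {
  fn <- params$functionals[[functional]]
  if (is.null(fn))
    d4_abort(sprintf("functional '%s' not present in parameter file", functional),
             "d4tune_config_error")
  structure(c(list(functional = functional), fn,
              list(q = params$q, c6 = params$c6)),
            class = "functional_params")
}

#' Path to the packaged water dispersion parameter file
#' @return File path of the H/O parameter set shipped with the package.
#' @export
d4_water_params_file <- function() {
  system.file("extdata", "d4_water_params.txt", package = "d4tune",
              mustWork = TRUE)
}

#' C8 dispersion coefficient from C6
#'
#' The octupole-order coefficient is derived recursively from the
#' dipole-dipole one: `C8ab = 3 C6ab sqrt(Qa Qb)`, with Q the element-wise
#' multipole ratio.
#'
#' @param c6 C6 coefficient (any consistent unit system).
#' @param qa,qb Multipole ratios of the two elements (> 0).
#' @return The C8 coefficient; units of `c6` times length^2.
#' @examples
#' c8_from_c6(1, 1, 1)  # 3
#' @export
c8_from_c6 <- function(c6, qa, qb) {
  if (any(c6 < 0)) d4_abort("C6 must be non-negative", "d4tune_domain_error")
  if (any(qa <= 0) || any(qb <= 0))
    d4_abort("q factors must be positive", "d4tune_domain_error")
  3 * c6 * sqrt(qa * qb)
}

#' Rational (Becke-Johnson) damping function
#'
#' `f_n(r) = r^n / (r^n + (sr_n (a1 sqrt(C8/C6) + a2))^n)`: switches the
#' `Cn/r^n` term off smoothly below the pair damping radius
#' `R0 = a1 sqrt(C8/C6) + a2`, avoiding the short-range singularity.
#'
#' @param r Interatomic distance(s), Angstrom; must be positive.
#' @param order Multipole order, 6 or 8.
#' @param c6,c8 Pair coefficients (consistent units; `c6 > 0` when `c8 > 0`).
#' @param a1 Dimensionless damping-radius scaling.
#' @param a2 Damping-radius offset, Angstrom.
#' @param sr Order-specific radius scaling (1 for n = 6; `sr8` for n = 8).
#' @return Damping factor(s) in [0, 1].
#' @export
bj_damping <- function(r, order, c6, c8, a1, a2, sr = 1) {
  if (any(r <= 0)) d4_abort("distances must be positive", "d4tune_domain_error")
  if (!order %in% c(6, 8)) d4_abort("order must be 6 or 8", "d4tune_domain_error")
  ratio <- ifelse(c8 > 0, c8 / c6, 0)
  r0 <- sr * (a1 * sqrt(ratio) + a2)
  rn <- r^order
  rn / (rn + r0^order)
}

#' Per-structure raw dispersion components
#'
#' Evaluates the damped two-body dispersion sums of one structure at unit
#' scaling factors, split by multipole order:
#' `e6_raw = sum_{a<b} C6ab f6(rab) / rab^6` and
#' `e8_raw = sum_{a<b} C8ab f8(rab) / rab^8` (kcal/mol, both non-negative).
#' Because the scaling factors enter the dispersion energy multiplicatively,
#' any `(S6, S8)` energy is the exact dot product
#' `S6 e6_raw + S8 e8_raw` — the linear decomposition the scaling-factor
#' refit exploits.
#'
#' @param s An [xyz_structure()].
#' @param fp A [functional_params()] object (or any list with `q`, `c6`,
#'   `a1`, `a2`, `sr8`).
#' @return One-row data.frame with `structure_id`, `e6_raw`, `e8_raw`.
#' @export
cluster_components <- function(s, fp) {
  n <- n_atoms(s)
  if (n < 2L)
    return(data.frame(structure_id = s$id, e6_raw = 0, e8_raw = 0,
                      stringsAsFactors = FALSE))
  missing_el <- setdiff(unique(s$elements), names(fp$q))
  if (length(missing_el))
    d4_abort(paste0("no dispersion parameters for element(s): ",
                    paste(missing_el, collapse = ", ")), "d4tune_config_error")
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  a <- pr[, 1L]; b <- pr[, 2L]
  dv <- s$xyz[a, , drop = FALSE] - s$xyz[b, , drop = FALSE]
  r <- sqrt(rowSums(dv^2))
  if (any(r <= 0))
    d4_abort("coincident atoms: zero interatomic distance", "d4tune_domain_error")
  ea <- s$elements[a]; eb <- s$elements[b]
  c6 <- fp$c6[cbind(ea, eb)]
  if (anyNA(c6)) {
    miss <- unique(paste(ea, eb)[is.na(c6)])
    d4_abort(paste0("missing C6 coefficient for pair(s): ",
                    paste(miss, collapse = "; ")), "d4tune_config_error")
  }
  c8 <- c8_from_c6(c6, fp$q[ea], fp$q[eb])
  f6 <- bj_damping(r, 6, c6, c8, fp$a1, fp$a2, sr = 1)
  f8 <- bj_damping(r, 8, c6, c8, fp$a1, fp$a2, sr = fp$sr8)
  data.frame(structure_id = s$id,
             e6_raw = sum(c6 * f6 / r^6),
             e8_raw = sum(c8 * f8 / r^8),
             stringsAsFactors = FALSE)
}

#' Dispersion components for a batch of structures
#'
#' @param structures List of [xyz_structure()] objects.
#' @inheritParams cluster_components
#' @return A data.frame with one row per structure (`structure_id`,
#'   `e6_raw`, `e8_raw`).
#' @export
components_table <- function(structures, fp) {
  if (!length(structures))
    return(data.frame(structure_id = character(), e6_raw = numeric(),
                      e8_raw = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(structures, cluster_components, fp = fp))
}

#' Dispersion energy from components and scaling factors
#'
#' `E_dis = S6 e6_raw + S8 e8_raw`, in kcal/mol, stored positive. Under the
#' sign convention used throughout the package the corrected total energy is
#' `E_DFT-D = E_DFT - E_dis` (many dispersion codes report the opposite
#' sign).
#'
#' @param comp Data.frame with columns `e6_raw`, `e8_raw` (one or more rows).
#' @param s6,s8 Scaling factors of the n = 6 and n = 8 terms.
#' @return Numeric vector of dispersion energies, kcal/mol.
#' @export
dispersion_energy <- function(comp, s6, s8) {
  s6 * comp$e6_raw + s8 * comp$e8_raw
}

#' Read a dispersion component table
#'
#' TSV with a `# units: kcal/mol` header and columns `structure_id`,
#' `e6_raw`, `e8_raw` — the ingestion path for components exported by an
#' external dispersion code. Negative raw components are recorded with a
#' validation warning but kept (damped two-body sums should be
#' non-negative).
#'
#' @param file Path to the TSV.
#' @return Data.frame of components.
#' @export
read_component_table <- function(file) {
  df <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("structure_id", "e6_raw", "e8_raw")
  miss <- setdiff(need, names(df))
  if (length(miss))
    d4_abort(paste0("component table missing column(s): ",
                    paste(miss, collapse = ", ")), "d4tune_format_error")
  if (any(df$e6_raw < 0 | df$e8_raw < 0))
    warning("component table contains negative raw components",
            call. = FALSE)
  df[need]
}

#' Write a dispersion component table
#' @param comp Data.frame with `structure_id`, `e6_raw`, `e8_raw`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_component_table <- function(comp, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# units: kcal/mol", con)
  writeLines("structure_id\te6_raw\te8_raw", con)
  if (nrow(comp))
    writeLines(sprintf("%s\t%.15g\t%.15g",
                       comp$structure_id, comp$e6_raw, comp$e8_raw), con)
  invisible(file)
}
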