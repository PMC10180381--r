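#' Harmonic water-monomer potential backend
#'
#' A built-in one-body potential: harmonic in the two O-H stretches and the
#' H-O-H bend about the reference gas-phase geometry,
#' `E = k_r/2 [(r1-r0)^2 + (r2-r0)^2] + k_theta/2 (theta-theta0)^2`.
#' Defaults approximate water's intramolecular force field
#' (O-H stretch ~8.4 mdyn/A, bend ~0.76 mdyn A/rad^2). Energies are relative
#' to the minimum at the reference geometry, so the backend evaluates to
#' exactly 0 there. It stands in for high-accuracy fitted monomer potentials
#' (e.g. Partridge-Schwenke) wherever per-monomer energies are not ingested
#' from a table.
#'
#' @param k_r Stretch force constant, kcal mol^-1 A^-2.
#' @param k_theta Bend force constant, kcal mol^-1 rad^-2.
#' @param ref A [ref_geometry()].
#' @return An object of class `monomer_backend` with an
#'   `evaluate(r1, r2, theta)` function (lengths in Angstrom, angle in
#'   degrees) returning kcal/mol.
#' @export
harmonic_backend <- function(k_r = 1210, k_theta = 109, ref = ref_geometry()) {
  force(k_r); force(k_theta); force(ref)
  structure(list(
    name = "harmonic",
    ref = ref,
    evaluate = function(r1, r2, theta) {
      dth <- (theta - ref$theta_hoh) * pi / 180
      0.5 * k_r * ((r1 - ref$r_oh)^2 + (r2 - ref$r_oh)^2) +
        0.5 * k_theta * dth^2
    }), class = "monomer_backend")
}

#' One-body (monomer deformation) energy sum
#'
#' Sums, over the monomers of a cluster, the energy of each isolated
#' (possibly distorted) monomer relative to the isolated molecule at the
#' reference gas-phase geometry: `sum_i [E(monomer_i) - E(ref)]`. Zero when
#' every monomer sits at the reference internal geometry.
#'
#' @param s An [xyz_structure()].
#' @param partition A [partition_monomers()] result for `s`.
#' @param backend A `monomer_backend` (e.g. [harmonic_backend()]).
#' @param ref Reference geometry at which the per-monomer baseline is
#'   evaluated (defaults to the backend's own reference).
#' @return One-body energy sum, kcal/mol.
#' @export
one_body_sum <- function(s, partition, backend, ref = backend$ref) {
  eref <- backend$evaluate(ref$r_oh, ref$r_oh, ref$theta_hoh)
  if (!is.finite(eref))
    d4_abort("backend is not finite at the reference geometry",
             "d4tune_domain_error")
  total <- 0
  for (k in seq_along(partition)) {
    ic <- monomer_internals(s, partition[[k]])
    e <- backend$evaluate(ic[["r1"]], ic[["r2"]], ic[["theta"]])
    if (!is.finite(e))
      d4_abort(sprintf("backend failed on monomer %d", k), "d4tune_domain_error")
    total <- total + (e - eref)
  }
  total
}

#' Per-monomer energies of a cluster under a backend
#'
#' @inheritParams one_body_sum
#' @return Numeric vector of absolute monomer energies (kcal/mol), one per
#'   monomer (not baseline-subtracted).
#' @export
monomer_energies <- function(s, partition, backend) {
  vapply(seq_along(partition), function(k) {
    ic <- monomer_internals(s, partition[[k]])
    backend$evaluate(ic[["r1"]], ic[["r2"]], ic[["theta"]])
  }, 0)
}

# ---- energy tables ---------------------------------------------------------

#' Read an energy table
#'
#' TSV with a `# units: kcal/mol` (or `# units: hartree`) header and columns
#' `structure_id`, `n_monomers`, `<method>__total`, optional
#' `<method>__ref_monomer` and `<method>__monomer_<i>`. Hartree energies are
#' converted to kcal/mol on input. When per-monomer columns are present for
#' a method, every row must carry exactly `n_monomers` finite entries.
#'
#' @param file Path to the TSV.
#' @return A list of energy records, each a list with `structure_id`,
#'   `n_monomers`, `e_total` (named by method), `e_ref_monomer` (named by
#'   method), `e_monomers` (named list of numeric vectors).
#' @export
read_energy_table <- function(file) {
  first <- readLines(file, n = 1L)
  units <- "kcal/mol"
  if (grepl("^#\\s*units\\s*:", first))
    units <- trimws(sub("^#\\s*units\\s*:", "", first))
  if (!units %in% c("kcal/mol", "hartree"))
    d4_abort(sprintf("unknown units '%s' in energy table", units),
             "d4tune_format_error")
  conv <- if (units == "hartree") d4_constants$hartree_kcal else 1
  df <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!all(c("structure_id", "n_monomers") %in% names(df)))
    d4_abort("energy table must have structure_id and n_monomers columns",
             "d4tune_format_error")
  ecols <- setdiff(names(df), c("structure_id", "n_monomers"))
  meth <- sub("__.*$", "", ecols)
  kind <- sub("^.*?__", "", ecols)  # part after the first "__"
  lapply(seq_len(nrow(df)), function(i) {
    n <- as.integer(df$n_monomers[i])
    if (is.na(n) || n < 1L)
      d4_abort(sprintf("row %d: invalid n_monomers", i), "d4tune_format_error")
    e_total <- c(); e_ref <- c(); e_mono <- list()
    for (m in unique(meth)) {
      sel <- meth == m
      k <- kind[sel]; cols <- ecols[sel]
      if ("total" %in% k)
        e_total[m] <- df[i, cols[k == "total"]] * conv
      if ("ref_monomer" %in% k)
        e_ref[m] <- df[i, cols[k == "ref_monomer"]] * conv
      mono_cols <- cols[grepl("^monomer_\\d+$", k)]
      if (length(mono_cols)) {
        ord <- order(as.integer(sub("^.*monomer_", "", mono_cols)))
        vals <- as.numeric(df[i, mono_cols[ord]])
        vals <- vals[is.finite(vals)]
        if (length(vals) != n)
          d4_abort(sprintf(
            "row %d: method %s has %d per-monomer energies but n_monomers = %d",
            i, m, length(vals), n), "d4tune_format_error")
        e_mono[[m]] <- vals * conv
      }
    }
    list(structure_id = as.character(df$structure_id[i]), n_monomers = n,
         e_total = e_total, e_ref_monomer = e_ref, e_monomers = e_mono)
  })
}

#' Write an energy table
#'
#' @param records List of energy records (see [read_energy_table()]).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_energy_table <- function(records, file) {
  methods <- unique(unlist(lapply(records, function(r) names(r$e_total))))
  nmax <- if (length(records))
    max(vapply(records, function(r)
      if (length(r$e_monomers)) max(lengths(r$e_monomers)) else 0L, 0L))
  else 0L
  header <- c("structure_id", "n_monomers")
  for (m in methods) {
    header <- c(header, paste0(m, "__total"), paste0(m, "__ref_monomer"))
    if (nmax > 0)
      header <- c(header, paste0(m, "__monomer_", seq_len(nmax)))
  }
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# units: kcal/mol", con)
  writeLines(paste(header, collapse = "\t"), con)
  for (r in records) {
    row <- c(r$structure_id, r$n_monomers)
    for (m in methods) {
      row <- c(row, sprintf("%.15g", r$e_total[[m]]),
               sprintf("%.15g", if (!is.null(r$e_ref_monomer[m]) &&
                                    !is.na(r$e_ref_monomer[m]))
                 r$e_ref_monomer[[m]] else 0))
      if (nmax > 0) {
        em <- r$e_monomers[[m]]
        pad <- c(sprintf("%.15g", em), rep("NA", nmax - length(em)))
        row <- c(row, pad)
      }
    }
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(file)
}

#' One-body sum of a method from an energy record
#'
#' `sum_i (E_X^i - E_X^ref)` read off the table columns of method `X`.
#'
#' @param rec An energy record (see [read_energy_table()]).
#' @param method Method label.
#' @return One-body energy sum, kcal/mol (0 when the record carries no
#'   per-monomer energies for the method).
#' @export
onebody_from_record <- function(rec, method) {
  em <- rec$e_monomers[[method]]
  if (is.null(em)) return(0)
  eref <- rec$e_ref_monomer[method]
  if (is.null(eref) || is.na(eref)) eref <- 0
  sum(em - eref)
}

# ---- deviations ------------------------------------------------------------

#' One-body-subtracted interaction-energy deviation of one cluster
#'
#' Bookkeeping for a single cluster configuration: the total
#' interaction-energy difference between a method and the benchmark,
#' `delta_total = [E_m^n - n E_m^ref] - [E_b^n - n E_b^ref]`, the one-body
#' deviation `delta_onebody = onebody_method - onebody_reference`, and their
#' difference `deviation = delta_total - delta_onebody`, which isolates the
#' intermolecular (beyond-one-body) part of the disagreement.
#'
#' @param rec An energy record carrying totals for both methods.
#' @param method Method label under scrutiny (e.g. a DFT functional).
#' @param reference_method Benchmark method label (e.g. `"MC"`).
#' @param onebody_method,onebody_reference One-body energy sums of the two
#'   methods, kcal/mol (from [one_body_sum()] or [onebody_from_record()]).
#' @return One-row data.frame: `structure_id`, `n_monomers`, `delta_total`,
#'   `delta_onebody`, `deviation`.
#' @export
interaction_deviation <- function(rec, method, reference_method,
                                  onebody_method = 0, onebody_reference = 0) {
  for (m in c(method, reference_method))
    if (!m %in% names(rec$e_total))
      d4_abort(sprintf("record '%s' has no total energy for method '%s'",
                       rec$structure_id, m), "d4tune_data_error")
  eref <- function(m) {
    v <- rec$e_ref_monomer[m]
    if (is.null(v) || is.na(v)) 0 else as.numeric(v)
  }
  n <- rec$n_monomers
  dm <- rec$e_total[[method]] - n * eref(method)
  db <- rec$e_total[[reference_method]] - n * eref(reference_method)
  delta_total <- dm - db
  delta_onebody <- onebody_method - onebody_reference
  data.frame(structure_id = rec$structure_id, n_monomers = n,
             delta_total = delta_total, delta_onebody = delta_onebody,
             deviation = delta_total - delta_onebody,
             stringsAsFactors = FALSE)
}

#' Assemble deviations for a batch of energy records
#'
#' Convenience wrapper running [interaction_deviation()] over a record list,
#' with one-body sums taken from the table columns (`onebody = "table"`) or
#' evaluated geometrically with a shared backend applied to both methods
#' (`onebody = "backend"`, which then cancels in `delta_onebody` only if the
#' same backend also produced the table; here it is applied per method).
#'
#' @param records List of energy records.
#' @param method,reference_method Method labels.
#' @param onebody `"table"` (default), `"none"`, or a `monomer_backend`
#'   applied to `structures`.
#' @param structures Optional list of [xyz_structure()] matching the records
#'   by `structure_id`; required when `onebody` is a backend.
#' @return Data.frame of deviation records.
#' @export
assemble_deviations <- function(records, method, reference_method,
                                onebody = "table", structures = NULL) {
  by_id <- NULL
  if (inherits(onebody, "monomer_backend")) {
    if (is.null(structures))
      d4_abort("structures are required for a geometric one-body backend",
               "d4tune_config_error")
    by_id <- stats::setNames(structures,
                             vapply(structures, function(s) s$id, ""))
  }
  if (!length(records))
    return(data.frame(structure_id = character(), n_monomers = integer(),
                      delta_total = numeric(), delta_onebody = numeric(),
                      deviation = numeric(), stringsAsFactors = FALSE))
  rows <- lapply(records, function(rec) {
    if (inherits(onebody, "monomer_backend")) {
      s <- by_id[[rec$structure_id]]
      if (is.null(s))
        d4_abort(sprintf("no structure for record '%s'", rec$structure_id),
                 "d4tune_data_error")
      ob <- one_body_sum(s, partition_monomers(s), onebody)
      obm <- ob; obr <- ob
    } else if (identical(onebody, "none")) {
      obm <- 0; obr <- 0
    } else {
      obm <- onebody_from_record(rec, method)
      obr <- onebody_from_record(rec, reference_method)
    }
    interaction_deviation(rec, method, reference_method, obm, obr)
  })
  do.call(rbind, rows)
}

#' Apply a dispersion correction to deviation records
#'
#' Shifts the method total by `-E_dis` (the corrected total being
#' `E_DFT - E_dis`), hence both `delta_total` and `deviation` decrease by
#' `S6 e6_raw + S8 e8_raw`; the one-body term is untouched.
#'
#' @param dev Data.frame of deviation records (see
#'   [interaction_deviation()]).
#' @param comp Component data.frame matching `dev` row-by-row via
#'   `structure_id`.
#' @param s6,s8 Scaling factors.
#' @return `dev` with shifted `delta_total` and `deviation`.
#' @export
apply_dispersion <- function(dev, comp, s6, s8) {
  idx <- match(dev$structure_id, comp$structure_id)
  if (anyNA(idx))
    d4_abort(paste0("no dispersion components for structure(s): ",
                    paste(dev$structure_id[is.na(idx)], collapse = ", ")),
             "d4tune_data_error")
  edis <- dispersion_energy(comp[idx, , drop = FALSE], s6, s8)
  dev$delta_total <- dev$delta_total - edis
  dev$deviation <- dev$deviation - edis
  dev
}
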