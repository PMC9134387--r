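#' Compute the molecular-descriptor table
#'
#' Computes an open set of 2D and 3D numeric descriptors for embedded
#' records: physicochemical properties through OpenBabel (molecular
#' weight, logP estimate, TPSA, H-bond acceptors/donors, molar
#' refractivity), topology counts (elements, rings, aromatic atoms and
#' bonds, rotatable bonds, charge-state proxies) and conformer geometry
#' (radius of gyration, span, principal-moment ratios, asphericity).
#' Every column is tagged with its source; descriptor failures for a
#' compound set the affected cells to `NA` with a log entry rather than
#' silently zeroing them.
#'
#' The table always includes the 11 chemical-space descriptors of
#' [chemical_space_descriptors()].
#'
#' @param records embedded `compound_library` (conformers required for the
#'   3D descriptors).
#' @return a `descriptor_table`: list with `compound_ids`, `data`
#'   (data.frame, one row per compound in input order) and `meta`
#'   (per-column `source` and `status`, all initially `"kept"`).
#' @export
compute_descriptors <- function(records) {
  ids <- vapply(records, `[[`, "", "compound_id")
  for (r in records)
    if (is.null(r$coords)) stop("compute_descriptors: no conformer for ", r$compound_id)

  sdf_txt <- unlist(lapply(records, function(r) c(r$molblock, "$$$$")))
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(sdf_txt, tf)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))

  ob_raw <- tryCatch(ChemmineR::propOB(sdfset), error = function(e) NULL)
  ob <- data.frame(MW = rep(NA_real_, length(records)), logP = NA_real_,
                   TPSA = NA_real_, HBA1 = NA_real_, HBA2 = NA_real_,
                   HBD = NA_real_, MR = NA_real_)
  if (!is.null(ob_raw)) {
    # align by molecule title: a failed molecule drops out of the result
    j <- match(ids, ob_raw$title)
    for (nm in names(ob)) ob[[nm]] <- ob_raw[[nm]][j]
    if (anyNA(j))
      sq_log("descriptors", "property calculation failed for %d compound(s); cells set missing",
             sum(is.na(j)))
  } else {
    sq_log("descriptors", "bulk property calculation failed; cells set missing")
  }

  per <- lapply(seq_along(records), function(i) {
    tryCatch(structural_descriptors(records[[i]], sdfset[[i]]),
             error = function(e) {
               sq_log("descriptors", "failure for %s: %s", ids[i], conditionMessage(e))
               NULL
             })
  })
  tmpl <- per[[which(!vapply(per, is.null, TRUE))[1L]]]
  per <- lapply(per, function(x) if (is.null(x)) stats::setNames(
    rep(NA_real_, length(tmpl)), names(tmpl)) else x)
  topo <- do.call(rbind, lapply(per, function(x) as.data.frame(as.list(x))))

  data <- cbind(
    data.frame(mw = ob$MW, slogp = ob$logP, tpsa = ob$TPSA, hba = ob$HBA2,
               hba_broad = ob$HBA1, hbd = ob$HBD, molar_refractivity = ob$MR),
    topo)
  # crude pH-7 distribution coefficient: logP penalized per ionizable group
  data$logd_proxy <- data$slogp - 2 * (topo$n_basic_n + topo$n_acidic_o)
  rownames(data) <- ids
  src <- c(rep("openbabel", 7L),
           ifelse(grepl("_3d$|^pmi_", names(topo)), "geometry3d", "topology"),
           "openbabel")
  meta <- data.frame(name = names(data), source = src, status = "kept",
                     stringsAsFactors = FALSE)
  structure(list(compound_ids = ids, data = data, meta = meta),
            class = "descriptor_table")
}

# Topology + geometry descriptors for one record.
structural_descriptors <- function(record, sdf) {
  el <- record$coords$element
  bonds <- record$bonds
  heavy <- el != "H"
  cnt <- function(e) sum(el == e)

  ring_info <- ChemmineR::rings(sdf, type = "all", arom = TRUE)
  ring_atoms <- lapply(ring_info$RINGS, function(r)
    as.integer(sub("^.*_", "", r)))
  arom <- unlist(ring_info$AROMATIC)
  n_rings <- length(ring_atoms)
  arom_atoms <- unique(unlist(ring_atoms[arom]))
  ring_bond_key <- unique(unlist(lapply(ring_atoms, function(a) {
    pairs <- cbind(a, c(a[-1L], a[1L]))
    paste(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
  })))
  arom_bond_key <- unique(unlist(lapply(ring_atoms[arom], function(a) {
    pairs <- cbind(a, c(a[-1L], a[1L]))
    paste(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
  })))

  bkey <- paste(pmin(bonds$from, bonds$to), pmax(bonds$from, bonds$to))
  heavy_deg <- tabulate(c(bonds$from[heavy[bonds$to]], bonds$to[heavy[bonds$from]]),
                        nbins = length(el))
  rot <- sum(bonds$order == 1L & heavy[bonds$from] & heavy[bonds$to] &
               !(bkey %in% ring_bond_key) &
               heavy_deg[bonds$from] >= 2L & heavy_deg[bonds$to] >= 2L)

  # crude charge-state proxies: aliphatic amine nitrogens and acidic
  # (carboxylic) carbons; net formal charge from the molblock CHG lines
  adj <- lapply(seq_along(el), function(i)
    c(bonds$to[bonds$from == i], bonds$from[bonds$to == i]))
  dbl_o <- vapply(seq_along(el), function(i) {
    nb <- bonds[bonds$from == i | bonds$to == i, , drop = FALSE]
    o <- ifelse(nb$from == i, nb$to, nb$from)
    any(el[o] == "O" & nb$order == 2L)
  }, TRUE)
  n_basic <- sum(el == "N" & !(seq_along(el) %in% arom_atoms) &
                   !vapply(adj, function(a) any(dbl_o[a] & el[a] == "C"), TRUE))
  n_acidic <- sum(vapply(seq_along(el), function(i) {
    if (el[i] != "C" || !dbl_o[i]) return(FALSE)
    a <- adj[[i]]
    any(el[a] == "O" & vapply(a, function(j)
      el[j] == "O" && any(el[adj[[j]]] == "H"), TRUE))
  }, TRUE))
  chg_lines <- grep("^M  CHG", record$molblock, value = TRUE)
  net_chg <- if (length(chg_lines)) sum(vapply(chg_lines, function(l) {
    f <- as.numeric(strsplit(trimws(sub("^M  CHG", "", l)), "\\s+")[[1L]])
    sum(f[seq(3L, length(f), by = 2L)])
  }, 0)) else 0

  xyz <- as.matrix(record$coords[, c("x", "y", "z")])
  c0 <- sweep(xyz, 2L, colMeans(xyz))
  gyr <- crossprod(c0) / nrow(c0)
  ev <- sort(eigen(gyr, symmetric = TRUE, only.values = TRUE)$values)
  tr <- sum(ev)
  c(n_atoms = length(el), n_heavy_atoms = sum(heavy), n_hydrogen = cnt("H"),
    n_carbon = cnt("C"), n_nitrogen = cnt("N"), n_oxygen = cnt("O"),
    n_sulfur = cnt("S"), n_fluorine = cnt("F"), n_chlorine = cnt("Cl"),
    n_bromine = cnt("Br"),
    n_halogen = cnt("F") + cnt("Cl") + cnt("Br") + cnt("I"),
    n_bonds = nrow(bonds), n_single_bonds = sum(bonds$order == 1L),
    n_double_bonds = sum(bonds$order == 2L),
    n_triple_bonds = sum(bonds$order == 3L),
    ring_count = n_rings, aromatic_ring_count = sum(arom),
    n_aromatic_atoms = length(arom_atoms),
    n_aromatic_bonds = length(arom_bond_key),
    n_rotatable_bonds = rot,
    n_basic_n = n_basic, n_acidic_o = n_acidic, net_formal_charge = net_chg,
    rgyr_3d = sqrt(mean(rowSums(c0^2))),
    span_3d = if (nrow(c0) > 1L) max(stats::dist(xyz)) else 0,
    asphericity_3d = if (tr > 0) (ev[3L] - 0.5 * (ev[1L] + ev[2L])) / tr else 0,
    pmi_ratio_1 = if (ev[3L] > 0) ev[1L] / ev[3L] else 0,
    pmi_ratio_2 = if (ev[3L] > 0) ev[2L] / ev[3L] else 0)
}

#' Apply the descriptor filtering rules
#'
#' Marks columns as removed when they are (a) non-numeric, (b) of zero
#' variance on the training rows (variance is never computed on test
#' rows, so adding test compounds cannot change the kept set), or (c)
#' named in `leakage_names` (features that would leak the endpoint).
#' Values of surviving columns are never altered, and the operation is
#' idempotent.
#'
#' @param table a `descriptor_table`.
#' @param training_ids ids of the training rows (must be a subset of the
#'   table's compounds).
#' @param leakage_names character vector of column names to remove as
#'   leakage risks; names not present produce a warning, not an error.
#' @return the table with updated `meta$status`.
#' @export
filter_descriptors <- function(table, training_ids, leakage_names = character()) {
  stopifnot(inherits(table, "descriptor_table"))
  if (!all(training_ids %in% table$compound_ids))
    stop("training_ids not all present in descriptor table")
  absent <- setdiff(leakage_names, table$meta$name)
  if (length(absent))
    warning("leakage name(s) not present: ", paste(absent, collapse = ", "))
  tr <- table$data[match(training_ids, table$compound_ids), , drop = FALSE]
  for (j in seq_along(table$data)) {
    nm <- table$meta$name[j]
    col <- tr[[j]]
    if (!is.numeric(col)) {
      table$meta$status[j] <- "non_numeric"
    } else if (nm %in% leakage_names) {
      table$meta$status[j] <- "leakage"
    } else {
      v <- col[is.finite(col)]
      if (length(v) == 0L || stats::var(v) == 0) table$meta$status[j] <- "zero_variance"
      else if (table$meta$status[j] %in% c("zero_variance", "non_numeric", "leakage"))
        table$meta$status[j] <- "kept"
    }
  }
  n_rm <- sum(table$meta$status != "kept" & table$meta$status != "reduced")
  sq_log("descriptors", "filter: %d kept, %d removed",
         sum(table$meta$status == "kept"), n_rm)
  table
}

#' Reduce the kept descriptor set to the top-k by importance
#'
#' Keeps the `k` kept columns of highest importance (ties broken by
#' lexicographic column name); the rest are marked `reduced`. Requesting
#' more columns than are kept keeps them all with a log entry.
#'
#' @param table a filtered `descriptor_table`.
#' @param importance named numeric importance covering all kept columns.
#' @param k number of columns to keep (>= 1).
#' @return the table with updated `meta$status`.
#' @export
reduce_to_top_k <- function(table, importance, k) {
  stopifnot(inherits(table, "descriptor_table"), k >= 1L)
  kept <- table$meta$name[table$meta$status == "kept"]
  if (!all(kept %in% names(importance)))
    stop("importance must cover all kept columns")
  if (k >= length(kept)) {
    sq_log("descriptors", "k=%d >= %d kept columns; keeping all", k, length(kept))
    return(table)
  }
  ord <- kept[order(-importance[kept], kept)]
  drop <- ord[(k + 1L):length(ord)]
  table$meta$status[table$meta$name %in% drop] <- "reduced"
  table
}

#' Matrix of kept descriptor columns
#'
#' @param table a `descriptor_table`.
#' @param ids optional id subset/order; defaults to all compounds.
#' @return numeric matrix, rownames = ids.
#' @export
kept_descriptor_matrix <- function(table, ids = NULL) {
  stopifnot(inherits(table, "descriptor_table"))
  if (is.null(ids)) ids <- table$compound_ids
  keep <- table$meta$name[table$meta$status == "kept"]
  m <- as.matrix(table$data[match(ids, table$compound_ids), keep, drop = FALSE])
  rownames(m) <- ids
  m
}

#' Write a descriptor table as CSV plus a sidecar metadata file
#'
#' @param table a `descriptor_table`.
#' @param path CSV path; the metadata (column source and filter status)
#'   goes to `<path>.meta.csv`.
#' @export
write_descriptor_table <- function(table, path) {
  out <- cbind(compound_id = table$compound_ids, table$data)
  utils::write.csv(out, path, row.names = FALSE)
  utils::write.csv(table$meta, paste0(path, ".meta.csv"), row.names = FALSE)
  invisible(path)
}
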