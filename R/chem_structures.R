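#' Compound record
#'
#' A lightweight container for one compound: identifier, connectivity
#' (SMILES), an optional single 3D conformer, and the regression endpoint.
#' The endpoint is a positive quantity (e.g. clearance in L/h/kg);
#' `log_endpoint` is always its base-10 logarithm. `class_label` is the
#' binary label obtained by thresholding the endpoint (see
#' [label_compounds()]).
#'
#' @param compound_id unique identifier string.
#' @param smiles connectivity string.
#' @param endpoint positive numeric endpoint value, or `NA`.
#' @param class_label optional binary label (0/1).
#' @return An object of class `compound_record`.
#' @export
compound_record <- function(compound_id, smiles, endpoint = NA_real_,
                            class_label = NA_integer_) {
  stopifnot(is.character(compound_id), length(compound_id) == 1L,
            is.character(smiles), length(smiles) == 1L)
  endpoint <- as.numeric(endpoint)
  if (!is.na(endpoint) && endpoint <= 0)
    stop("endpoint must be positive (log transform undefined): ", compound_id)
  structure(list(
    compound_id = compound_id,
    smiles = smiles,
    endpoint = endpoint,
    log_endpoint = if (is.na(endpoint)) NA_real_ else log10(endpoint),
    class_label = as.integer(class_label),
    coords = NULL,      # data.frame(element, x, y, z) once embedded
    bonds = NULL,       # data.frame(from, to, order)
    molblock = NULL,    # V2000 molblock lines (normalized header)
    render_flag = "ok"
  ), class = "compound_record")
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<compound_record %s> %s endpoint=%s atoms=%s\n",
              x$compound_id, x$smiles,
              format(x$endpoint),
              if (is.null(x$coords)) "-" else nrow(x$coords)))
  invisible(x)
}

# ---- molblock helpers -------------------------------------------------------

# OpenBabel stamps line 2 of a molblock with its name + creation date; the
# date part makes otherwise identical structures differ byte-wise between
# days. Normalize it so SDF output and content-addressed caches are stable.
normalize_molblock <- function(lines) {
  if (length(lines) >= 2L) lines[2L] <- " snapqsar          3D"
  lines
}

# Parse one V2000 molblock (character vector of lines, no "$$$$") into
# coords and bonds. Fixed-width per the CTfile spec.
parse_molblock <- function(lines) {
  counts <- lines[4L]
  na <- as.integer(substr(counts, 1L, 3L))
  nb <- as.integer(substr(counts, 4L, 6L))
  if (is.na(na) || na < 1L) stop("malformed molblock counts line")
  at <- lines[4L + seq_len(na)]
  coords <- data.frame(
    element = trimws(substr(at, 32L, 34L)),
    x = as.numeric(substr(at, 1L, 10L)),
    y = as.numeric(substr(at, 11L, 20L)),
    z = as.numeric(substr(at, 21L, 30L)),
    stringsAsFactors = FALSE
  )
  bonds <- if (nb > 0L) {
    bl <- lines[4L + na + seq_len(nb)]
    data.frame(
      from = as.integer(substr(bl, 1L, 3L)),
      to = as.integer(substr(bl, 4L, 6L)),
      order = as.integer(substr(bl, 7L, 9L))
    )
  } else data.frame(from = integer(), to = integer(), order = integer())
  if (any(!is.finite(coords$x + coords$y + coords$z)))
    stop("non-finite coordinates in molblock")
  list(coords = coords, bonds = bonds)
}

# Split concatenated SDF text into per-molecule molblock line vectors,
# keyed by the title line. Records the molecule order of the file.
split_sdf_text <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  ends <- which(lines == "$$$$")
  out <- list()
  start <- 1L
  for (e in ends) {
    blk <- lines[start:(e - 1L)]
    # drop trailing data fields; molblock ends at "M  END"
    m <- which(blk == "M  END")
    if (length(m)) {
      mol <- normalize_molblock(blk[1:m[1L]])
      out[[length(out) + 1L]] <- mol
    }
    start <- e + 1L
  }
  out
}

# ---- parse_library ----------------------------------------------------------

#' Read a compound library from a SMILES table or SDF file
#'
#' For `format = "smiles"` the file is a delimited table (whitespace or
#' comma) with a SMILES column and, optionally, endpoint and identifier
#' columns. For `format = "sdf"` a V2000 SDF file is read; 3D coordinates
#' present in the file populate each record's conformer, and the endpoint
#' is taken from the named SDF data field when given.
#'
#' Molecules that fail to parse are rejected, counted and logged; they do
#' not abort the run. An empty file is an error.
#'
#' @param path input file path.
#' @param format `"smiles"` or `"sdf"`.
#' @param endpoint_field name of the endpoint column (SMILES table) or SDF
#'   data field; `NULL` for none. For headerless SMILES tables, column 2 is
#'   the endpoint when present.
#' @param id_field optional identifier column/field name; defaults to the
#'   SMILES-table third column or the SDF title, falling back to `CMP<i>`.
#' @param header logical; does the SMILES table have a header line?
#' @param sep field separator for SMILES tables; default splits on commas
#'   or whitespace.
#' @return list of [compound_record()] objects, in input order, with
#'   attribute `rejected` (data.frame of rejected inputs and reasons).
#' @export
parse_library <- function(path, format = c("smiles", "sdf"),
                          endpoint_field = NULL, id_field = NULL,
                          header = FALSE, sep = "[,[:space:]]+") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  if (format == "smiles") parse_smiles_table(path, endpoint_field, id_field, header, sep)
  else parse_sdf_library(path, endpoint_field, id_field)
}

parse_smiles_table <- function(path, endpoint_field, id_field, header, sep) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty SMILES table: ", path)
  cols <- c("smiles", "endpoint", "id")
  if (header) {
    cols <- strsplit(trimws(lines[1L]), sep)[[1L]]
    lines <- lines[-1L]
    if (length(lines) == 0L) stop("SMILES table has a header but no rows: ", path)
  }
  parts <- strsplit(trimws(lines), sep)
  smi_col <- if (header && "smiles" %in% tolower(cols)) which(tolower(cols) == "smiles")[1L] else 1L
  ep_col <- if (!is.null(endpoint_field) && endpoint_field %in% cols)
    which(cols == endpoint_field)[1L] else if (is.null(endpoint_field)) 2L else NA_integer_
  id_col <- if (!is.null(id_field) && id_field %in% cols) which(cols == id_field)[1L] else 3L

  smi <- vapply(parts, function(p) if (length(p) >= smi_col) p[smi_col] else NA_character_, "")
  ok_smi <- validate_smiles(smi)
  rejected <- data.frame(input = character(), reason = character())
  records <- list()
  for (i in seq_along(smi)) {
    p <- parts[[i]]
    if (is.na(smi[i]) || !ok_smi[i]) {
      rejected <- rbind(rejected, data.frame(input = lines[i], reason = "unparsable SMILES"))
      next
    }
    ep <- if (!is.na(ep_col) && length(p) >= ep_col) suppressWarnings(as.numeric(p[ep_col])) else NA_real_
    id <- if (length(p) >= id_col) p[id_col] else sprintf("CMP%d", i)
    rec <- tryCatch(compound_record(id, smi[i], ep),
                    error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      rejected <- rbind(rejected, data.frame(input = lines[i], reason = rec))
      next
    }
    records[[length(records) + 1L]] <- rec
  }
  if (nrow(rejected) > 0L)
    sq_log("parse", "rejected %d of %d input molecules", nrow(rejected), length(smi))
  check_unique_ids(records)
  structure(records, rejected = rejected, class = "compound_library")
}

# Batch-validate SMILES strings through OpenBabel canonicalization; a
# molecule that cannot be canonicalized is invalid.
validate_smiles <- function(smiles) {
  ok <- !is.na(smiles) & nzchar(smiles)
  idx <- which(ok)
  if (length(idx) == 0L) return(ok)
  inp <- paste0(smiles[idx], " q", idx, "\n", collapse = "")
  out <- suppressWarnings(suppressMessages(
    ChemmineOB::convertFormat("SMI", "CAN", source = inp)))
  got <- strsplit(out, "\n", fixed = TRUE)[[1L]]
  tags <- sub("^.*\\s", "", got[nzchar(got)])
  seen <- paste0("q", idx) %in% tags
  ok[idx] <- seen
  ok
}

parse_sdf_library <- function(path, endpoint_field, id_field) {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  if (length(sdfset) == 0L) stop("empty SDF file: ", path)
  valid <- ChemmineR::validSDF(sdfset)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  blocks <- split_sdf_text(paste0(txt, "\n"))
  rejected <- data.frame(input = character(), reason = character())
  records <- list()
  for (i in seq_along(sdfset)) {
    if (!valid[i]) {
      rejected <- rbind(rejected, data.frame(
        input = sprintf("molecule %d", i), reason = "invalid SDF record"))
      next
    }
    sdf <- sdfset[[i]]
    hdr <- ChemmineR::header(sdf)
    db <- ChemmineR::datablock(sdf)
    id <- if (!is.null(id_field) && id_field %in% names(db)) db[[id_field]]
          else if (nzchar(trimws(hdr[1L]))) trimws(hdr[1L]) else sprintf("CMP%d", i)
    ep <- if (!is.null(endpoint_field) && endpoint_field %in% names(db))
      suppressWarnings(as.numeric(db[[endpoint_field]])) else NA_real_
    rec <- compound_record(id, sdf_to_smiles(blocks[[i]]), ep)
    parsed <- parse_molblock(blocks[[i]])
    rec$coords <- parsed$coords
    rec$bonds <- parsed$bonds
    rec$molblock <- blocks[[i]]
    records[[length(records) + 1L]] <- rec
  }
  if (nrow(rejected) > 0L)
    sq_log("parse", "rejected %d of %d SDF records", nrow(rejected), length(sdfset))
  check_unique_ids(records)
  structure(records, rejected = rejected, class = "compound_library")
}

sdf_to_smiles <- function(molblock) {
  out <- suppressWarnings(suppressMessages(ChemmineOB::convertFormat(
    "SDF", "CAN", source = paste0(paste(molblock, collapse = "\n"), "\n$$$$\n"))))
  smi <- strsplit(trimws(out), "\\s+")[[1L]][1L]
  if (is.na(smi) || !nzchar(smi)) "" else smi
}

check_unique_ids <- function(records) {
  ids <- vapply(records, `[[`, "", "compound_id")
  if (anyDuplicated(ids))
    stop("duplicate compound_id in library: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  invisible(ids)
}

#' @export
print.compound_library <- function(x, ...) {
  cat(sprintf("<compound_library> %d compounds (%d rejected at parse)\n",
              length(x), nrow(attr(x, "rejected") %||% data.frame())))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- conformer embedding ----------------------------------------------------

# Run the bundled distance-geometry embedder on (id, smiles, seed) rows;
# returns molblock line vectors named by id (absent = embedding failed).
embed_molblocks <- function(ids, smiles, seeds) {
  script <- system.file("python", "embed_conformers.py", package = "snapqsar")
  if (!nzchar(script)) stop("bundled embedding helper not found")
  inp <- tempfile(fileext = ".tsv")
  out <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(inp, out)), add = TRUE)
  writeLines(paste(ids, smiles, seeds, sep = "\t"), inp)
  status <- suppressWarnings(system2(getOption("snapqsar.python", "python"),
                                     c(shQuote(script), shQuote(inp), shQuote(out)),
                                     stdout = FALSE, stderr = FALSE))
  if (status != 0L || !file.exists(out))
    stop("conformer embedding helper failed (python + rdkit required)")
  txt <- paste(readLines(out, warn = FALSE), collapse = "\n")
  blocks <- split_sdf_text(paste0(txt, "\n"))
  stats::setNames(blocks, vapply(blocks, function(b) trimws(b[1L]), ""))
}

#' Generate one 3D conformer for a compound
#'
#' Builds explicit-hydrogen 3D coordinates from the record's connectivity
#' by distance-geometry embedding (ETKDG) followed by MMFF94 force-field
#' minimization, producing a single low-energy conformer. Salts and
#' counter-ions are stripped to the largest covalently bonded fragment
#' before building (logged when it happens). Embedding is a pure function
#' of (connectivity, seed): repeated calls with the same seed give
#' bitwise-identical coordinates, whether run singly or in a batch.
#'
#' @param record a [compound_record()].
#' @param seed integer random seed for the distance-geometry embedding.
#' @param retries retry attempts on embedding failure; each retry
#'   perturbs the seed by a fixed offset.
#' @return the record with `coords`, `bonds` and `molblock` populated, or
#'   with `render_flag = "unrenderable"` if embedding failed.
#' @export
embed_conformer <- function(record, seed = 1L, retries = 2L) {
  stopifnot(inherits(record, "compound_record"))
  smi <- strip_to_largest_fragment(record$smiles, record$compound_id)
  for (attempt in 0:retries) {
    blocks <- embed_molblocks(record$compound_id, smi,
                              as.integer(seed) + 1000L * attempt)
    if (record$compound_id %in% names(blocks)) {
      mb <- blocks[[record$compound_id]]
      parsed <- parse_molblock(mb)
      record$coords <- parsed$coords
      record$bonds <- parsed$bonds
      record$molblock <- mb
      record$render_flag <- "ok"
      return(record)
    }
  }
  sq_log("embed", "embedding failed for %s after %d attempts; flagged un-renderable",
         record$compound_id, retries + 1L)
  record$render_flag <- "unrenderable"
  record
}

# Keep only the largest dot-separated SMILES fragment (heavy-atom heuristic
# by fragment string length; ties broken by first occurrence).
strip_to_largest_fragment <- function(smiles, id = "") {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1L]]
  if (length(frags) <= 1L) return(smiles)
  heavy <- nchar(gsub("[^A-Za-z]", "", gsub("H", "", frags)))
  keep <- frags[which.max(heavy)]
  sq_log("embed", "stripped %d counter-ion fragment(s) from %s", length(frags) - 1L, id)
  keep
}

#' Embed conformers for a whole library
#'
#' Batch variant of [embed_conformer()]: one embedder invocation for the
#' whole library. Each molecule is embedded independently at the same
#' seed, so batch coordinates are identical to per-record calls; records
#' missing from the batch output are retried singly and flagged
#' un-renderable on persistent failure.
#'
#' @param records a `compound_library` or list of records.
#' @param seed integer seed (see [embed_conformer()]).
#' @return the library with conformers populated.
#' @export
embed_library <- function(records, seed = 1L) {
  smis <- vapply(records, function(r) strip_to_largest_fragment(r$smiles), "")
  ids <- vapply(records, `[[`, "", "compound_id")
  blocks <- embed_molblocks(ids, smis, rep(as.integer(seed), length(ids)))
  for (i in seq_along(records)) {
    if (!ids[i] %in% names(blocks)) {
      records[[i]] <- embed_conformer(records[[i]], seed = seed)
      next
    }
    mb <- blocks[[ids[i]]]
    parsed <- parse_molblock(mb)
    records[[i]]$coords <- parsed$coords
    records[[i]]$bonds <- parsed$bonds
    records[[i]]$molblock <- mb
    records[[i]]$render_flag <- "ok"
  }
  n_bad <- sum(vapply(records, `[[`, "", "render_flag") == "unrenderable")
  sq_log("embed", "embedded %d/%d compounds (%d un-renderable)",
         length(records) - n_bad, length(records), n_bad)
  records
}

# ---- write_sdf --------------------------------------------------------------

#' Write records to batched SDF V2000 files
#'
#' Writes each record's conformer as one SDF molecule (title = compound_id,
#' endpoint stored in an `<endpoint>` data field), splitting the output into
#' files of at most `batch_size` molecules.
#'
#' @param records list of embedded [compound_record()]s.
#' @param path output file path; when more than one batch is needed the
#'   files are numbered `<stem>_001.sdf`, `<stem>_002.sdf`, ...
#' @param batch_size maximum molecules per file (default 100).
#' @return invisibly, the character vector of files written.
#' @export
write_sdf <- function(records, path, batch_size = 100L) {
  if (length(records) == 0L) stop("write_sdf: no records to write")
  stopifnot(batch_size >= 1L)
  for (r in records)
    if (is.null(r$coords) || is.null(r$molblock))
      stop("write_sdf: record without coordinates: ", r$compound_id)
  n <- length(records)
  n_files <- ceiling(n / batch_size)
  files <- if (n_files == 1L) path else {
    stem <- sub("\\.sdf$", "", path)
    sprintf("%s_%03d.sdf", stem, seq_len(n_files))
  }
  for (f in seq_len(n_files)) {
    idx <- ((f - 1L) * batch_size + 1L):min(f * batch_size, n)
    txt <- unlist(lapply(records[idx], function(r) {
      mb <- r$molblock
      mb[1L] <- r$compound_id
      c(mb,
        if (!is.na(r$endpoint)) c(">  <endpoint>", format(r$endpoint, digits = 15), ""),
        "$$$$")
    }))
    writeLines(txt, files[f])
  }
  sq_log("sdf", "wrote %d molecules to %d file(s)", n, n_files)
  invisible(files)
}
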