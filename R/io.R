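#' @keywords internal
"_PACKAGE"

# Column names of the 16 fold-change periods, fc_01 .. fc_16.
fc_columns <- function() sprintf("fc_%02d", 1:16)

COMPOUND_CLASSES <- c("prototype", "metabolite")
HERB_ORIGINS <- c("RA", "RG", "BOTH", "UNKNOWN")

#' Read or write a herbnet TSV table
#'
#' All tabular artifacts are tab-separated files with a header row.
#' Lines starting with `#` are metadata comments (config hash, seed) and
#' are skipped on read.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @param comments Character vector of metadata lines to embed, each
#'   written as a `#`-prefixed comment before the header.
#' @return `read_tsv()` returns a data.frame; `write_tsv()` returns
#'   `path` invisibly.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
}

#' @rdname read_tsv
#' @export
write_tsv <- function(x, path, comments = character()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(comments) > 0) {
    writeLines(paste0("# ", comments), con, sep = "\n")
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a compound table
#'
#' Parses a TSV of herb constituents, one row per compound, with columns
#' `compound_id`, `name`, `structure` (SMILES, may be empty),
#' `compound_class` (`prototype` or `metabolite`), `herb_origin`
#' (`RA`, `RG`, `BOTH`, `UNKNOWN`) and the sixteen fold-change columns
#' `fc_01` .. `fc_16`.  Missing fold-change periods are encoded as empty
#' cells and kept as `NA`, never as zero.  An optional `fc_max` column is
#' validated against the row-wise maximum; when absent it is computed.
#' An optional `class_tags` column carries comma-separated curation tags
#' used by the screening blocklist.
#'
#' @param path Path to the TSV file.
#' @return A validated data.frame with one row per compound, numeric
#'   `fc_01` .. `fc_16` columns and a numeric `fc_max` column.
#' @export
read_compound_table <- function(path) {
  x <- read_tsv(path)
  validate_compound_table(x, source = path)
}

#' @rdname read_compound_table
#' @param x A data.frame shaped like a compound table.
#' @param source Label used in error messages.
#' @export
validate_compound_table <- function(x, source = "compound table") {
  required <- c("compound_id", "name", "structure", "compound_class",
                "herb_origin", fc_columns())
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s", source,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(x$compound_id)) {
    stop(sprintf("%s: duplicated compound_id", source), call. = FALSE)
  }
  for (col in fc_columns()) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad) > 0) {
        stop(sprintf("%s: non-numeric value in column %s at row %d",
                     source, col, bad[1]), call. = FALSE)
      }
      x[[col]] <- num
    }
    if (any(x[[col]] < 0, na.rm = TRUE)) {
      stop(sprintf("%s: negative fold change in column %s", source, col),
           call. = FALSE)
    }
  }
  if (!all(x$compound_class %in% COMPOUND_CLASSES)) {
    stop(sprintf("%s: compound_class must be one of %s", source,
                 paste(COMPOUND_CLASSES, collapse = ", ")), call. = FALSE)
  }
  if (!all(x$herb_origin %in% HERB_ORIGINS)) {
    stop(sprintf("%s: herb_origin must be one of %s", source,
                 paste(HERB_ORIGINS, collapse = ", ")), call. = FALSE)
  }
  bad_unknown <- x$herb_origin == "UNKNOWN" & x$compound_class == "prototype"
  if (any(bad_unknown)) {
    stop(sprintf("%s: herb_origin UNKNOWN is only allowed for metabolites (%s)",
                 source, paste(x$compound_id[bad_unknown], collapse = ", ")),
         call. = FALSE)
  }
  fc <- as.matrix(x[, fc_columns()])
  observed_max <- apply(fc, 1, function(r) {
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
  })
  if ("fc_max" %in% names(x)) {
    stated <- as.numeric(x$fc_max)
    mismatch <- which(!is.na(stated) & !is.na(observed_max) &
                        abs(stated - observed_max) > 1e-8)
    if (length(mismatch) > 0) {
      stop(sprintf(
        "%s: fc_max column inconsistent with fc series at row %d (%s): stated %g, series max %g",
        source, mismatch[1], x$compound_id[mismatch[1]],
        stated[mismatch[1]], observed_max[mismatch[1]]), call. = FALSE)
    }
  }
  x$fc_max <- observed_max
  if (!"class_tags" %in% names(x)) x$class_tags <- ""
  x$class_tags[is.na(x$class_tags)] <- ""
  x$structure[is.na(x$structure)] <- ""
  x
}

#' Read gene sets from a GMT file
#'
#' One gene set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Gene symbols are uppercased and deduplicated.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (one per set); each element
#'   carries the set description in its `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("%s: line %d has fewer than 3 fields", path, i),
           call. = FALSE)
    }
    genes <- normalize_gene_symbols(fields[-(1:2)])
    attr(genes, "description") <- fields[2]
    nms[i] <- fields[1]
    sets[[i]] <- genes
  }
  names(sets) <- nms
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    desc <- attr(sets[[i]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(names(sets)[i], desc, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Normalize gene symbols
#'
#' Uppercases, trims whitespace and deduplicates symbols, optionally
#' rewriting aliases through a two-column map (`alias`, `symbol`).  No
#' remote lookup is performed; the alias map is a plain offline TSV.
#'
#' @param genes Character vector of symbols.
#' @param alias_map Optional data.frame with columns `alias` and `symbol`.
#' @return Character vector of unique, uppercase official symbols.
#' @export
normalize_gene_symbols <- function(genes, alias_map = NULL) {
  g <- toupper(trimws(as.character(genes)))
  g <- g[nzchar(g)]
  if (!is.null(alias_map)) {
    key <- toupper(trimws(alias_map$alias))
    val <- toupper(trimws(alias_map$symbol))
    hit <- match(g, key)
    g[!is.na(hit)] <- val[hit[!is.na(hit)]]
  }
  unique(g)
}

#' Read a one-column gene list
#'
#' @param path Path to a text file with one gene symbol per line
#'   (`#` comments allowed).
#' @return Character vector of unique uppercase symbols.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#")]
  normalize_gene_symbols(lines)
}

#' @rdname read_gene_list
#' @param genes Character vector of gene symbols.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Read bioactivity measurements
#'
#' TSV with columns `compound_id`, `target_gene`, `measure_kind`
#' (Ki/Kd/IC50/EC50), `value_uM` (positive, micromolar) and `source`.
#'
#' @param path Path to the TSV file.
#' @return A validated data.frame of measurements.
#' @export
read_activity_table <- function(path) {
  x <- read_tsv(path)
  required <- c("compound_id", "target_gene", "measure_kind", "value_uM")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  kinds <- c("Ki", "Kd", "IC50", "EC50")
  if (!all(x$measure_kind %in% kinds)) {
    stop(sprintf("%s: measure_kind must be one of %s", path,
                 paste(kinds, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(x$value_uM) | x$value_uM <= 0)) {
    bad <- which(!is.finite(x$value_uM) | x$value_uM <= 0)[1]
    stop(sprintf("%s: non-positive activity value at row %d", path, bad),
         call. = FALSE)
  }
  x$target_gene <- toupper(trimws(x$target_gene))
  if (!"source" %in% names(x)) x$source <- ""
  x
}

#' Read compound fingerprints
#'
#' TSV with columns `compound_id` and `keys`, where `keys` is a
#' comma-separated list of substructure-key identifiers (e.g. bits of a
#' structural fingerprint dictionary).
#'
#' @param path Path to the TSV file.
#' @return A named list mapping compound id to a character vector of keys.
#' @export
read_fingerprints <- function(path) {
  x <- read_tsv(path)
  if (!all(c("compound_id", "keys") %in% names(x))) {
    stop(sprintf("%s: fingerprint table needs columns compound_id, keys",
                 path), call. = FALSE)
  }
  fp <- lapply(x$keys, function(k) {
    if (is.na(k) || !nzchar(k)) character(0)
    else unique(trimws(strsplit(k, ",", fixed = TRUE)[[1]]))
  })
  names(fp) <- x$compound_id
  fp
}

#' @rdname read_fingerprints
#' @param fingerprints Named list of key vectors.
#' @export
write_fingerprints <- function(fingerprints, path) {
  x <- data.frame(
    compound_id = names(fingerprints),
    keys = vapply(fingerprints, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  write_tsv(x, path)
}

#' Read a compound/drug-target edge list
#'
#' TSV with columns `compound_id` and `target_gene`; an optional `origin`
#' column (`known`/`predicted`) and optional `score` column are preserved.
#'
#' @param path Path to the TSV file.
#' @return Data.frame of unique edges.
#' @export
read_cti_table <- function(path) {
  x <- read_tsv(path)
  if (!all(c("compound_id", "target_gene") %in% names(x))) {
    stop(sprintf("%s: edge list needs columns compound_id, target_gene",
                 path), call. = FALSE)
  }
  x$target_gene <- toupper(trimws(x$target_gene))
  x
}

#' Read a protein-protein interaction edge list
#'
#' TSV with two gene-symbol columns `gene_a` and `gene_b`.  Self loops
#' and duplicate (unordered) pairs are dropped.
#'
#' @param path Path to the TSV file.
#' @return Data.frame with columns `gene_a`, `gene_b`.
#' @export
read_ppi_edges <- function(path) {
  x <- read_tsv(path)
  if (!all(c("gene_a", "gene_b") %in% names(x))) {
    stop(sprintf("%s: PPI edge list needs columns gene_a, gene_b", path),
         call. = FALSE)
  }
  a <- toupper(trimws(x$gene_a))
  b <- toupper(trimws(x$gene_b))
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  key <- ifelse(a < b, paste(a, b), paste(b, a))
  dup <- duplicated(key)
  data.frame(gene_a = a[!dup], gene_b = b[!dup], stringsAsFactors = FALSE)
}

#' Read a docking-score table
#'
#' TSV with columns `compound_id`, `target_gene`, `gscore` (docking
#' score; more negative indicates stronger predicted binding).
#'
#' @param path Path to the TSV file.
#' @return Data.frame of docking records.
#' @export
read_dock_table <- function(path) {
  x <- read_tsv(path)
  required <- c("compound_id", "target_gene", "gscore")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  x$target_gene <- toupper(trimws(x$target_gene))
  x$gscore <- as.numeric(x$gscore)
  if (any(!is.finite(x$gscore))) {
    stop(sprintf("%s: non-numeric gscore", path), call. = FALSE)
  }
  x
}
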