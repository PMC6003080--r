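#' Construct an AbundanceTable
#'
#' @param values numeric matrix, samples x features, with dimnames.
#' @param normalized logical or `NA`; when `NA` (default) the flag is
#'   auto-detected: a table whose every row sums to 1 within 1e-6 is
#'   treated as already holding relative abundances.
#' @param lineages optional named character vector of lineage strings
#'   (names = OTU feature ids), as captured from an embedded taxonomy
#'   column.
#' @return An [AbundanceTable-class].
#' @export
abundanceTable <- function(values, normalized = NA, lineages = character()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.na(normalized))
    normalized <- nrow(values) > 0 && all(abs(rowSums(values) - 1) <= 1e-6)
  if (normalized) {
    rs <- rowSums(values)
    if (any(rs == 0))
      stop("all-zero sample(s): ",
           paste(utils::head(rownames(values)[rs == 0], 3), collapse = ", "))
    values <- values / rs  # snap near-1 rows to exactly 1
  }
  methods::new("AbundanceTable", values = values,
               normalized = isTRUE(normalized), lineages = lineages)
}

#' Read an OTU table (classic QIIME TSV or BIOM v1 JSON)
#'
#' Classic tables are OTUs x samples on disk with a `"#OTU ID"` header
#' (preceding `#` comment lines allowed) and an optional trailing
#' `taxonomy` column; BIOM v1 JSON (dense or sparse) is read through the
#' biomformat package. Either way the result is transposed to the
#' in-memory samples x features orientation, counts preserved exactly,
#' and any per-OTU taxonomy strings are captured in the `lineages` slot.
#'
#' @param path file path; format is chosen by `format` or sniffed
#'   (leading `{` means BIOM v1 JSON).
#' @param format one of `"auto"`, `"tsv"`, `"biom"`.
#' @param normalized passed to [abundanceTable()] (`NA` = auto-detect
#'   counts vs relative abundances; use TRUE/FALSE to override).
#' @return An [AbundanceTable-class].
#' @export
readOtuTable <- function(path, format = c("auto", "tsv", "biom"),
                         normalized = NA) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readChar(path, 1L)
    format <- if (identical(first, "{")) "biom" else "tsv"
  }
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    mat <- as(biomformat::biom_data(b), "matrix")  # OTUs x samples
    lin <- character()
    md <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
    if (!is.null(md)) {
      tx <- if (is.data.frame(md)) {
        apply(md, 1L, paste, collapse = "; ")
      } else {
        vapply(md, function(r) paste(unlist(r), collapse = "; "), character(1))
      }
      lin <- stats::setNames(as.character(tx), rownames(mat))
    }
    return(abundanceTable(t(mat), normalized = normalized, lineages = lin))
  }
  lines <- readLines(path)
  hdrAt <- grep("^#OTU ID\t", lines)[1]
  if (is.na(hdrAt))
    stop("not a classic OTU table: no '#OTU ID' header line in ", path)
  header <- strsplit(lines[hdrAt], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  hasTax <- length(samples) > 0 &&
    tolower(samples[length(samples)]) == "taxonomy"
  if (hasTax) samples <- samples[-length(samples)]
  if (anyDuplicated(samples))
    stop("duplicate sample id in header: ", samples[duplicated(samples)][1])
  body <- lines[-seq_len(hdrAt)]
  body <- body[nzchar(body)]
  otus <- character(length(body))
  lin <- if (hasTax) character(length(body)) else character()
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(samples))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    lineNo <- hdrAt + i
    if (length(f) != length(header))
      stop("ragged row at line ", lineNo, ": expected ", length(header),
           " fields, got ", length(f))
    otus[i] <- f[1]
    num <- suppressWarnings(as.numeric(f[2:(length(samples) + 1L)]))
    if (anyNA(num))
      stop("non-numeric abundance at line ", lineNo, ": '",
           f[2:(length(samples) + 1L)][which(is.na(num))[1]], "'")
    vals[i, ] <- num
    if (hasTax) lin[i] <- f[length(f)]
  }
  if (anyDuplicated(otus))
    stop("duplicate OTU id: ", otus[duplicated(otus)][1])
  dimnames(vals) <- list(otus, samples)
  if (hasTax) names(lin) <- otus
  abundanceTable(t(vals), normalized = normalized, lineages = lin)
}

#' Read a 2-column taxonomy mapping (OTU id, lineage string)
#'
#' The classic Greengenes taxonomy file dialect: tab-separated, no header
#' (lines starting with `#` are skipped).
#'
#' @param path file path.
#' @return named character vector of lineage strings.
#' @export
readTaxonomyFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("taxonomy line ", bad[1], " has no lineage column")
  stats::setNames(vapply(parts, `[`, character(1), 2L),
                  vapply(parts, `[`, character(1), 1L))
}

#' Read a sample label file
#'
#' Tab-separated `sample_id <TAB> class`; `#`-prefixed lines (e.g. a
#' QIIME mapping header) are skipped.
#'
#' @param path file path.
#' @return named factor, sample id -> class, with >= 2 levels expected
#'   downstream.
#' @export
readLabels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stop("label line ", bad[1], " has no class column")
  ids <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate sample id in labels: ", ids[duplicated(ids)][1])
  stats::setNames(factor(vapply(parts, `[`, character(1), 2L)), ids)
}

#' Check that labels cover a table's samples
#' @return factor aligned to sampleIds(table).
#' @noRd
.alignLabels <- function(table, labels) {
  if (!is.factor(labels))
    labels <- stats::setNames(factor(labels), names(labels))
  miss <- setdiff(sampleIds(table), names(labels))
  if (length(miss))
    stop("no label for sample(s): ", paste(utils::head(miss, 3), collapse = ", "))
  droplevels(labels[sampleIds(table)])
}

#' Convert a table to per-sample relative abundances
#'
#' Divides every sample row by its total so rows sum to 1. Idempotent on
#' already-normalized tables; rejects all-zero samples by name.
#'
#' @param table an [AbundanceTable-class].
#' @return a normalized [AbundanceTable-class].
#' @export
normalizeRelative <- function(table) {
  stopifnot(methods::is(table, "AbundanceTable"))
  if (isNormalized(table)) return(table)
  v <- abundances(table)
  rs <- rowSums(v)
  if (any(rs == 0))
    stop("cannot normalize all-zero sample(s): ",
         paste(utils::head(rownames(v)[rs == 0], 3), collapse = ", "))
  methods::new("AbundanceTable", values = v / rs, normalized = TRUE,
               lineages = table@lineages)
}

#' Write an engineered feature table
#'
#' One row per sample, one column per feature plus a trailing `class`
#' column. Values are relative abundances multiplied by `scale`
#' (default 1e5, the convention used for published engineered feature
#' sets) and printed with two decimals; with `scale = 1` raw relative
#' abundances are written at full precision.
#'
#' @param table an [AbundanceTable-class] holding relative abundances —
#'   either a normalized table or a column subset of one (a selected
#'   feature set's rows need not sum to 1).
#' @param labels named factor/character of per-sample classes.
#' @param path output file path.
#' @param scale positive multiplier applied before printing.
#' @param metadata optional data.frame of extra per-sample columns
#'   (rownames = sample ids), appended unscaled between the features and
#'   the class column — selection never sees them.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(table, labels, path, scale = 1e5,
                              metadata = NULL) {
  stopifnot(methods::is(table, "AbundanceTable"), scale > 0)
  cls <- .alignLabels(table, labels)
  v <- abundances(table) * scale
  if (!is.null(metadata)) {
    miss <- setdiff(rownames(v), rownames(metadata))
    if (length(miss))
      stop("no metadata for sample(s): ",
           paste(utils::head(miss, 3), collapse = ", "))
    metadata <- metadata[rownames(v), , drop = FALSE]
  }
  fmt <- if (scale == 1) function(x) format(x, digits = 15, scientific = FALSE,
                                            trim = TRUE)
         else function(x) sprintf("%.2f", x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#SampleID", colnames(v), colnames(metadata), "class"),
                   collapse = "\t"), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(rownames(v)[i], fmt(v[i, ]),
                       if (!is.null(metadata))
                         vapply(metadata[i, , drop = FALSE], as.character,
                                character(1)),
                       as.character(cls[i])),
                     collapse = "\t"), con)
  invisible(path)
}

#' Write a classic OTU table (OTUs x samples TSV)
#'
#' @param table an [AbundanceTable-class] (in-memory samples x features).
#' @param path output file path.
#' @param lineages optional named character of lineage strings; when given
#'   (or present in the table), written as a trailing `taxonomy` column.
#' @return `path`, invisibly.
#' @export
writeOtuTable <- function(table, path, lineages = NULL) {
  stopifnot(methods::is(table, "AbundanceTable"))
  if (is.null(lineages) && length(table@lineages)) lineages <- table@lineages
  v <- t(abundances(table))  # back to OTUs x samples on disk
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("#OTU ID", colnames(v), if (!is.null(lineages)) "taxonomy")
  writeLines(paste(hdr, collapse = "\t"), con)
  num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  for (i in seq_len(nrow(v))) {
    row <- c(rownames(v)[i], num(v[i, ]),
             if (!is.null(lineages)) unname(lineages[rownames(v)[i]]))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}
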