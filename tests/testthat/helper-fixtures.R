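# Shared fixtures, built in code.

# Three OTUs: two complete under genus G, one stopping at the same family
# (a leaf in an incomplete path).
tinyLineages <- function() c(
  otu1 = "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae; g__Blautia; s__producta",
  otu2 = "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae; g__Blautia; s__obeum",
  otu3 = "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae"
)

tinyTree <- function() buildTaxonomy(names(tinyLineages()), tinyLineages())

# Classic OTU-table TSV on disk (OTUs x samples), optional taxonomy column
writeTinyOtuTsv <- function(path, taxonomy = FALSE) {
  lines <- c(
    "# Constructed from a test fixture",
    paste(c("#OTU ID", "S1", "S2", if (taxonomy) "taxonomy"), collapse = "\t"),
    paste(c("otu1", "2", "6", if (taxonomy) tinyLineages()[["otu1"]]), collapse = "\t"),
    paste(c("otu2", "3", "0", if (taxonomy) tinyLineages()[["otu2"]]), collapse = "\t"),
    paste(c("otu3", "5", "4", if (taxonomy) tinyLineages()[["otu3"]]), collapse = "\t"))
  writeLines(lines, path)
  path
}

# Same table as BIOM v1 JSON (sparse)
writeTinyBiom <- function(path) {
  counts <- rbind(otu1 = c(2, 6), otu2 = c(3, 0), otu3 = c(5, 4))
  triplets <- which(counts != 0, arr.ind = TRUE)
  data <- lapply(seq_len(nrow(triplets)), function(i)
    c(triplets[i, 1] - 1L, triplets[i, 2] - 1L,
      counts[triplets[i, 1], triplets[i, 2]]))
  biom <- list(
    id = "tiny", format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org",
    type = "OTU table", generated_by = "taxhfe tests",
    date = "2026-01-01T00:00:00",
    matrix_type = "sparse", matrix_element_type = "int",
    shape = c(3L, 2L),
    rows = lapply(rownames(counts), function(id)
      list(id = id, metadata = NULL)),
    columns = list(list(id = "S1", metadata = NULL),
                   list(id = "S2", metadata = NULL)),
    data = data)
  jsonlite::write_json(biom, path, auto_unbox = TRUE, digits = NA, null = "null")
  path
}

# samples x features AbundanceTable straight from a matrix
makeTable <- function(values, normalized = NA) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%d", seq_len(nrow(values)))
  abundanceTable(values, normalized = normalized)
}

# Binary-valued feature column with a controlled information gain:
# nLeft/nRight samples take values 0/1, with `aLeft` of class A on the
# left. Labels are balanced A/B overall.
splitColumn <- function(n, aLeft, nLeft) {
  labels <- factor(rep(c("A", "B"), each = n / 2))
  col <- numeric(n)
  aIdx <- which(labels == "A"); bIdx <- which(labels == "B")
  left <- c(aIdx[seq_len(aLeft)], bIdx[seq_len(nLeft - aLeft)])
  col[setdiff(seq_len(n), left)] <- 1
  list(values = col, labels = labels)
}
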