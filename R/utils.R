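# Internal helpers shared across modules.

# canonical column sets for the plain data.frame currencies of the package
.BLOCK_COLS <- c("ref_id", "qry_id", "ref_start", "ref_end",
                 "qry_start", "qry_end", "strand", "match_len", "identity")

.HIT_COLS <- c("query_id", "subject_id", "identity", "aln_len", "mismatch",
               "gapopen", "qstart", "qend", "sstart", "send", "evalue",
               "bitscore")

.REPEAT_COLS <- c("seqid", "start", "end", "rclass", "family", "run_id")

# Table-2 repeat class vocabulary; every annotation must land in one of these.
.REPEAT_CLASSES <- c("Tandem", "Simple", "Satellite", "DNA", "RC", "LINE",
                     "LTR", "rRNA", "snRNA", "tRNA", "Unknown")

.BUSCO_STATUSES <- c("Complete", "Duplicated", "Fragmented", "Missing")

.emptyBlocks <- function() {
  data.frame(ref_id = character(), qry_id = character(),
             ref_start = integer(), ref_end = integer(),
             qry_start = integer(), qry_end = integer(),
             strand = character(), match_len = integer(),
             identity = numeric(), stringsAsFactors = FALSE)
}

.checkBlocks <- function(blocks) {
  stopifnot(is.data.frame(blocks))
  missing <- setdiff(.BLOCK_COLS, names(blocks))
  if (length(missing))
    stop("alignment block table lacks column(s): ",
         paste(missing, collapse = ", "))
  invisible(blocks)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# join/split for set-valued columns written to TSV
.joinIds <- function(ids) {
  vapply(ids, function(v) if (length(v)) paste(sort(v), collapse = ",") else "",
         character(1))
}

.splitIds <- function(x) {
  lapply(x, function(s) if (is.na(s) || !nzchar(s)) character(0)
         else strsplit(s, ",", fixed = TRUE)[[1]])
}

# minimal union-find used for cross-run family clustering
.unionFind <- function(n) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  list(
    find = find,
    union = function(i, j) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <<- rj
      invisible(NULL)
    },
    components = function() vapply(seq_len(n), find, integer(1))
  )
}

#' Read or write a headered TSV
#'
#' All tabular pipeline outputs are plain headered TSVs; these wrappers fix
#' the dialect (tab separator, no quoting, no row names, `NA` as empty) so
#' that `writeTsv()` followed by `readTsv()` is the identity on the tables
#' the pipeline emits.
#'
#' @param x A data.frame.
#' @param path File path.
#' @return `readTsv()` returns a data.frame; `writeTsv()` returns `path`
#'   invisibly.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = NULL, check.names = FALSE)
}
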