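# Readers and writers for the external formats the pipeline touches.
#
# Internal coordinate convention: half-open, 0-based everywhere except at
# the GFF3 / BUSCO-table boundaries, which keep their native 1-based
# inclusive coordinates (GFF features are held in GRanges, whose native
# convention is 1-based inclusive).  Dialect conversions happen exactly
# once, inside the reader/writer pair, and are covered by round-trip tests.

#' Read a genome assembly from FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()] and normalizes to the package's
#' conventions: record order is preserved, sequences are uppercased
#' (soft-masking is discarded; masking state is re-derived from repeat
#' tables downstream), the scaffold id is the first whitespace-delimited
#' header token and any remainder is kept as a description.
#'
#' @param path FASTA file.
#' @return A named `DNAStringSet`; descriptions in `mcols(x)$description`.
#' @export
readAssembly <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0)
    stop("no FASTA records in ", path)
  hdr <- names(seqs)
  ids <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (any(!nzchar(ids)))
    stop("empty sequence id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  names(seqs) <- ids
  S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(description = desc)
  seqs
}

#' Write a genome assembly to FASTA
#'
#' Inverse of [readAssembly()]; descriptions stored in
#' `mcols(x)$description` are appended to the header line.
#'
#' @param x A named `DNAStringSet`.
#' @param path Output file.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
writeAssembly <- function(x, path, width = 70) {
  stopifnot(is(x, "DNAStringSet"), !is.null(names(x)))
  out <- x
  desc <- S4Vectors::mcols(x)$description
  if (!is.null(desc)) {
    keep <- !is.na(desc) & nzchar(desc)
    names(out)[keep] <- paste(names(x)[keep], desc[keep])
  }
  Biostrings::writeXStringSet(out, path, width = width)
  invisible(path)
}

.parseGffAttributes <- function(attr, key) {
  pat <- paste0("(?:^|;)\\s*", key, "=([^;]*)")
  m <- regexpr(pat, attr, perl = TRUE)
  val <- rep(NA_character_, length(attr))
  hit <- m > 0
  val[hit] <- sub(pat, "\\1", regmatches(attr, m), perl = TRUE)
  val
}

#' Read a GFF3 annotation into a GRanges
#'
#' `##` directives and comment lines are skipped; feature order follows the
#' file. Coordinates stay 1-based inclusive (the GRanges convention). The
#' `ID` and `Parent` attributes are lifted into metadata columns; the full
#' attribute string is kept verbatim for round-tripping. Feature types other
#' than gene/mRNA/exon/CDS are retained untouched.
#'
#' @param path GFF3 file.
#' @param seqLens Optional named vector of scaffold lengths; when given,
#'   features extending beyond their scaffold raise an error.
#' @return A `GRanges` with metadata columns `source`, `type`, `score`,
#'   `phase`, `ID`, `Parent`, `attributes`.
#' @export
readAnnotation <- function(path, seqLens = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(GenomicRanges::GRanges(
      seqnames = character(), ranges = IRanges::IRanges(),
      source = character(), type = character(), score = character(),
      phase = character(), ID = character(), Parent = character(),
      attributes = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 9))
    stop("malformed GFF line ", lineno[which(nf < 9)[1]], ": expected 9 ",
         "tab-separated columns, found ", nf[which(nf < 9)[1]])
  m <- matrix(unlist(lapply(parts, `[`, 1:9)), ncol = 9, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end))
    stop("non-numeric coordinate at GFF line ",
         lineno[which(is.na(start) | is.na(end))[1]])
  bad <- which(end < start)
  if (length(bad))
    stop("end < start at GFF line ", lineno[bad[1]], " (",
         m[bad[1], 4], " > ", m[bad[1], 5], ")")
  if (!is.null(seqLens)) {
    over <- which(end > seqLens[m[, 1]] | is.na(seqLens[m[, 1]]))
    if (length(over))
      stop("feature at GFF line ", lineno[over[1]],
           " extends beyond scaffold ", m[over[1], 1])
  }
  strand <- m[, 7]
  strand[!strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(
    seqnames = m[, 1],
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand,
    source = m[, 2], type = m[, 3], score = m[, 6], phase = m[, 8],
    ID = .parseGffAttributes(m[, 9], "ID"),
    Parent = .parseGffAttributes(m[, 9], "Parent"),
    attributes = m[, 9])
}

#' Write a GRanges annotation to GFF3
#'
#' Inverse of [readAnnotation()]: the `attributes` metadata column is
#' written verbatim (falling back to `ID`/`Parent` when absent), so a
#' read/write cycle is the identity.
#'
#' @param gr A `GRanges` as returned by [readAnnotation()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  attrs <- mc$attributes
  if (is.null(attrs)) {
    attrs <- ifelse(is.na(mc$ID), ".", paste0("ID=", mc$ID))
    hasP <- !is.na(mc$Parent)
    attrs[hasP] <- paste0(attrs[hasP], ";Parent=", mc$Parent[hasP])
  }
  st <- as.character(BiocGenerics::strand(gr))
  st[st == "*"] <- "."
  lines <- paste(as.character(GenomicRanges::seqnames(gr)),
                 if (is.null(mc$source)) "hapcull" else mc$source,
                 mc$type,
                 BiocGenerics::start(gr), BiocGenerics::end(gr),
                 if (is.null(mc$score)) "." else mc$score,
                 st,
                 if (is.null(mc$phase)) "." else mc$phase,
                 attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a benchmark-gene full table
#'
#' Parses the tab-separated "full table" emitted by BUSCO-style benchmark
#' analyses: one row per benchmark gene placement with columns id, status,
#' scaffold, start, end, (strand,) score, length. Both the 7-column (no
#' strand) and 8+-column (with strand) layouts are accepted; `#` header
#' lines are skipped. Missing genes keep an empty placement.
#'
#' @param path Full-table TSV.
#' @return data.frame with columns `busco_id`, `status`, `seqid`, `start`,
#'   `end`, `strand`, `score`, `length` (coordinates 1-based inclusive, NA
#'   for Missing).
#' @export
readBuscoTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  empty <- data.frame(busco_id = character(), status = character(),
                      seqid = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), length = integer(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(seq_along(parts), function(i) {
    p <- trimws(parts[[i]])
    status <- p[2]
    if (!status %in% .BUSCO_STATUSES)
      stop("unknown benchmark status '", status, "' in row ", i, " of ", path)
    if (status == "Missing" || length(p) < 5) {
      return(data.frame(busco_id = p[1], status = status, seqid = "",
                        start = NA_integer_, end = NA_integer_,
                        strand = NA_character_, score = NA_real_,
                        length = NA_integer_, stringsAsFactors = FALSE))
    }
    hasStrand <- length(p) >= 8 || (length(p) >= 6 && p[6] %in% c("+", "-"))
    strand <- if (hasStrand) p[6] else NA_character_
    score <- suppressWarnings(as.numeric(if (hasStrand) p[7] else p[6]))
    len <- suppressWarnings(as.integer(if (hasStrand) p[8] else p[7]))
    data.frame(busco_id = p[1], status = status, seqid = p[3],
               start = as.integer(p[4]), end = as.integer(p[5]),
               strand = strand, score = score, length = len,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a benchmark-gene full table
#'
#' @param busco data.frame as returned by [readBuscoTable()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
writeBuscoTable <- function(busco, path) {
  fmt <- function(x) ifelse(is.na(x), "", as.character(x))
  lines <- ifelse(
    busco$status == "Missing",
    paste(busco$busco_id, busco$status, sep = "\t"),
    paste(busco$busco_id, busco$status, busco$seqid, fmt(busco$start),
          fmt(busco$end), fmt(busco$strand), fmt(busco$score),
          fmt(busco$length), sep = "\t"))
  writeLines(c("# Busco id\tStatus\tSequence\tGene Start\tGene End\tStrand\tScore\tLength",
               lines), path)
  invisible(path)
}

#' Read pairwise alignments into alignment blocks
#'
#' Supports two dialects: PAF (minimap2-style; already 0-based half-open)
#' and the tab-separated output of `show-coords -T` (1-based inclusive;
#' antisense rows have the query interval reversed). All blocks are
#' normalized to the internal convention: half-open 0-based with
#' `qry_start < qry_end`, and strand `sense`/`antisense`.
#'
#' @param path Alignment file.
#' @param dialect `"paf"` or `"coords"`.
#' @param seqLens Optional named lengths used to validate coordinates (PAF
#'   carries its own declared lengths, which are always checked).
#' @return data.frame of alignment blocks with columns `ref_id`, `qry_id`,
#'   `ref_start`, `ref_end`, `qry_start`, `qry_end`, `strand`, `match_len`,
#'   `identity`.
#' @export
readAlignments <- function(path, dialect = c("paf", "coords"),
                           seqLens = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "paf") {
    if (!length(lines)) return(.emptyBlocks())
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 12))
      stop("PAF rows need >= 12 columns")
    g <- function(i, as = as.character) as(vapply(parts, `[`, "", i))
    qname <- g(1); qlen <- g(2, as.integer)
    qstart <- g(3, as.integer); qend <- g(4, as.integer)
    strand <- g(5)
    tname <- g(6); tlen <- g(7, as.integer)
    tstart <- g(8, as.integer); tend <- g(9, as.integer)
    nmatch <- g(10, as.integer); alen <- g(11, as.integer)
    if (any(qend > qlen) || any(tend > tlen))
      stop("alignment coordinate outside declared sequence length")
    blocks <- data.frame(
      ref_id = tname, qry_id = qname,
      ref_start = tstart, ref_end = tend,
      qry_start = qstart, qry_end = qend,
      strand = ifelse(strand == "-", "antisense", "sense"),
      match_len = nmatch,
      identity = ifelse(alen > 0, nmatch / alen, 0),
      stringsAsFactors = FALSE)
  } else {
    # skip any non-numeric preamble (show-coords banner/header)
    firstField <- sub("\\s.*$", "", trimws(lines))
    lines <- lines[grepl("^-?[0-9]+$", firstField)]
    if (!length(lines)) return(.emptyBlocks())
    parts <- strsplit(trimws(lines), "[\t ]+")
    if (any(lengths(parts) < 9))
      stop("coords rows need >= 9 columns (use show-coords -T)")
    g <- function(i, as = as.character) as(vapply(parts, `[`, "", i))
    s1 <- g(1, as.integer); e1 <- g(2, as.integer)
    s2 <- g(3, as.integer); e2 <- g(4, as.integer)
    idy <- g(7, as.numeric) / 100
    refId <- g(8); qryId <- g(9)
    anti <- s2 > e2
    qs <- ifelse(anti, e2, s2) - 1L
    qe <- ifelse(anti, s2, e2)
    blocks <- data.frame(
      ref_id = refId, qry_id = qryId,
      ref_start = s1 - 1L, ref_end = e1,
      qry_start = qs, qry_end = qe,
      strand = ifelse(anti, "antisense", "sense"),
      match_len = as.integer(round(pmin(e1 - s1 + 1L, abs(e2 - s2) + 1L) *
                                     idy)),
      identity = idy,
      stringsAsFactors = FALSE)
  }
  if (!is.null(seqLens)) {
    bad <- blocks$ref_end > seqLens[blocks$ref_id] |
      blocks$qry_end > seqLens[blocks$qry_id]
    if (any(bad, na.rm = TRUE) || anyNA(bad))
      stop("alignment coordinate outside declared sequence length")
  }
  blocks
}

#' Write alignment blocks as PAF
#'
#' @param blocks Alignment block data.frame.
#' @param path Output file.
#' @param qryLens,refLens Named sequence lengths for the PAF length columns;
#'   defaults to the largest end coordinate seen per sequence.
#' @return `path`, invisibly.
#' @export
writeAlignments <- function(blocks, path, qryLens = NULL, refLens = NULL) {
  .checkBlocks(blocks)
  lenOf <- function(given, ids, ends) {
    if (!is.null(given)) return(unname(given[ids]))
    vapply(ids, function(i) max(ends[ids == i]), numeric(1))
  }
  ql <- lenOf(qryLens, blocks$qry_id, blocks$qry_end)
  rl <- lenOf(refLens, blocks$ref_id, blocks$ref_end)
  span <- pmax(blocks$ref_end - blocks$ref_start,
               blocks$qry_end - blocks$qry_start)
  lines <- paste(blocks$qry_id, ql, blocks$qry_start, blocks$qry_end,
                 ifelse(blocks$strand == "antisense", "-", "+"),
                 blocks$ref_id, rl, blocks$ref_start, blocks$ref_end,
                 blocks$match_len, span, 255L, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read tabular similarity hits
#'
#' Parses the 12-column tabular hit dialect (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore). Self-hits are
#' retained; downstream scoring excludes them.
#'
#' @param path Hit TSV (headerless).
#' @return data.frame with columns `query_id`, `subject_id`, `identity`,
#'   `aln_len`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bitscore`.
#' @export
readHits <- function(path) {
  first <- readLines(path, n = 1)
  if (!length(first)) {
    out <- as.data.frame(setNames(rep(list(character(0)), 12), .HIT_COLS))
    return(out)
  }
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 12)
    stop("hit table must have exactly 12 columns, found ", ncol(df))
  names(df) <- .HIT_COLS
  df$identity <- as.numeric(df$identity)
  df$bitscore <- as.numeric(df$bitscore)
  df$evalue <- as.numeric(df$evalue)
  df
}

#' Write tabular similarity hits
#'
#' @param hits data.frame as returned by [readHits()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeHits <- function(hits, path) {
  stopifnot(all(.HIT_COLS %in% names(hits)))
  utils::write.table(hits[, .HIT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Mapping from RepeatMasker class strings to the repeat-class vocabulary
#'
#' The accounting vocabulary has eleven classes (Tandem, Simple, Satellite,
#' DNA, RC, LINE, LTR, rRNA, snRNA, tRNA, Unknown). RepeatMasker `.out`
#' class/family strings are mapped on the text before the first `/`;
#' `Low_complexity` is folded into `Simple`, and anything unmappable is
#' recorded as `Unknown` with a warning (never dropped).
#'
#' @return Named character vector: RepeatMasker class -> vocabulary class.
#' @export
rmClassMap <- function() {
  c(LINE = "LINE", LTR = "LTR", DNA = "DNA", RC = "RC",
    Simple_repeat = "Simple", Low_complexity = "Simple",
    Satellite = "Satellite", rRNA = "rRNA", snRNA = "snRNA",
    tRNA = "tRNA", Tandem = "Tandem", Unknown = "Unknown",
    Unspecified = "Unknown")
}

#' Read a repeat annotation table
#'
#' Two dialects: RepeatMasker `.out` (whitespace-separated, three header
#' lines; class strings mapped through [rmClassMap()]) and Tandem Repeat
#' Finder `.dat` (per-sequence `Sequence:` headers followed by numeric
#' rows, annotated as class `Tandem`). Coordinates are normalized to
#' half-open 0-based.
#'
#' @param path Input file.
#' @param dialect `"rmout"` or `"trf"`.
#' @param runId Provenance label stored in the `run_id` column.
#' @return data.frame with columns `seqid`, `start`, `end`, `rclass`,
#'   `family`, `run_id`.
#' @export
readRepeatTable <- function(path, dialect = c("rmout", "trf"), runId = "") {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  empty <- data.frame(seqid = character(), start = integer(),
                      end = integer(), rclass = character(),
                      family = character(), run_id = character(),
                      stringsAsFactors = FALSE)
  if (dialect == "rmout") {
    dat <- lines[grepl("^\\s*[0-9]", lines)]
    if (!length(dat)) return(empty)
    parts <- strsplit(trimws(dat), "\\s+")
    if (any(lengths(parts) < 11))
      stop("RepeatMasker .out rows need >= 11 columns")
    g <- function(i) vapply(parts, `[`, "", i)
    classfam <- g(11)
    cls <- sub("/.*$", "", classfam)
    fam <- g(10)
    map <- rmClassMap()
    rclass <- unname(map[cls])
    un <- is.na(rclass)
    if (any(un)) {
      warning("unmappable repeat class(es) recorded as Unknown: ",
              paste(unique(cls[un]), collapse = ", "))
      rclass[un] <- "Unknown"
    }
    data.frame(seqid = g(5),
               start = as.integer(g(6)) - 1L,
               end = as.integer(g(7)),
               rclass = rclass, family = fam,
               run_id = runId, stringsAsFactors = FALSE)
  } else {
    seqid <- NA_character_
    out <- list()
    for (ln in lines) {
      if (grepl("^Sequence:", ln)) {
        seqid <- trimws(sub("^Sequence:", "", ln))
        seqid <- sub("\\s.*$", "", seqid)
      } else if (grepl("^[0-9]+ [0-9]+ [0-9]+", ln)) {
        p <- strsplit(trimws(ln), "\\s+")[[1]]
        if (is.na(seqid))
          stop("TRF data row before any 'Sequence:' header")
        out[[length(out) + 1L]] <- data.frame(
          seqid = seqid, start = as.integer(p[1]) - 1L,
          end = as.integer(p[2]), rclass = "Tandem",
          family = paste0("trf-period", p[3]),
          run_id = runId, stringsAsFactors = FALSE)
      }
    }
    if (!length(out)) return(empty)
    do.call(rbind, out)
  }
}

#' Write a repeat annotation table in RepeatMasker .out layout
#'
#' Counterpart of `readRepeatTable(dialect = "rmout")`; used by the
#' synthetic generator so its emissions parse through the same reader.
#'
#' @param annotations Repeat annotation data.frame (internal coordinates).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeRepeatTable <- function(annotations, path) {
  stopifnot(all(c("seqid", "start", "end", "rclass", "family") %in%
                  names(annotations)))
  hdr <- c(
    "   SW   perc perc perc  query     position in query    matching  repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat    class/family",
    "")
  lines <- sprintf("  250   5.0  0.0  0.0  %s  %d  %d  (0)  +  %s  %s/%s  1  100  (0)  %d",
                   annotations$seqid, annotations$start + 1L,
                   annotations$end, annotations$family,
                   annotations$rclass, annotations$family,
                   seq_len(nrow(annotations)))
  writeLines(c(hdr, lines), path)
  invisible(path)
}
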