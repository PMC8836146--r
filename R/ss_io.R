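#' Minimum continuously observed residues under the 95% coverage rule
#'
#' A protein is admitted to the analysis only if an experimentally solved
#' structure continuously covers at least 95% of its sequence, unobserved
#' residues being allowed only at the termini. This returns the smallest
#' number of observed residues that admits a sequence of the given length,
#' i.e. \eqn{\lceil 0.95 L \rceil}.
#'
#' The ceiling is computed in exact integer arithmetic
#' (\eqn{\lceil 19L/20 \rceil}) so that boundary lengths are never
#' misclassified by floating-point representation of 0.95.
#'
#' @param seq_length Positive integer vector of sequence lengths in amino
#'   acids.
#' @return Integer vector: minimum observed-residue counts.
#' @examples
#' min_required_observed(c(14, 33, 75)) # 14 32 72
#' @export
min_required_observed <- function(seq_length) {
  if (length(seq_length) == 0) stop("`seq_length` must be non-empty", call. = FALSE)
  if (anyNA(seq_length) || any(seq_length < 1) || any(seq_length != floor(seq_length))) {
    stop("`seq_length` must contain positive integers", call. = FALSE)
  }
  as.integer((19 * as.numeric(seq_length) + 19) %/% 20)
}

#' Test coverage records against the 95% continuous-coverage filter
#'
#' Coverage is modelled as a single continuously observed interval in
#' 1-based inclusive residue coordinates; records with internal gaps are not
#' representable and must be rejected upstream.
#'
#' @param coverage A data frame with columns `accession`, `seq_length`,
#'   `observed_start`, `observed_end` (1-based inclusive).
#' @return Logical vector, one element per record: `TRUE` iff the observed
#'   interval contains at least `min_required_observed(seq_length)` residues.
#' @seealso [min_required_observed()]
#' @export
passes_coverage <- function(coverage) {
  req <- c("accession", "seq_length", "observed_start", "observed_end")
  if (!is.data.frame(coverage) || !all(req %in% names(coverage))) {
    stop("`coverage` must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  s <- coverage$observed_start
  e <- coverage$observed_end
  L <- coverage$seq_length
  if (anyNA(s) || anyNA(e) || anyNA(L)) stop("coverage records contain NA", call. = FALSE)
  if (any(s < 1) || any(s > e) || any(e > L)) {
    stop("invalid coverage record: need 1 <= observed_start <= observed_end <= seq_length",
         call. = FALSE)
  }
  (e - s + 1L) >= min_required_observed(L)
}

#' Mean secondary-structure length of one protein
#'
#' @param lengths Numeric vector of segment lengths in amino acids
#'   (at least one segment).
#' @return The arithmetic mean segment length.
#' @examples
#' mean_ss_length(c(29, 15, 20)) # 21.333...
#' @export
mean_ss_length <- function(lengths) {
  if (length(lengths) == 0) stop("protein has zero secondary-structure segments", call. = FALSE)
  if (anyNA(lengths) || any(lengths < 1)) {
    stop("segment lengths must be >= 1 amino acid", call. = FALSE)
  }
  mean(lengths)
}

# Internal: build the canonical protein tibble from parsed pieces.
# Only helix (H) and strand (E) tokens count as secondary structures; any
# other annotation kind is dropped and counted in the `n_ignored_segments`
# attribute.
build_protein_tbl <- function(accession, seq_length, locations, seg_lengths, seg_kinds,
                              n_excluded = 0L, n_ignored = 0L) {
  x <- vapply(seg_lengths, length, integer(1))
  y <- vapply(seg_lengths, mean, numeric(1))
  out <- tibble::tibble(
    accession = accession,
    seq_length = as.integer(seq_length),
    locations = locations,
    seg_lengths = seg_lengths,
    seg_kinds = seg_kinds,
    x = as.integer(x),
    y = y
  )
  attr(out, "n_excluded_zero_segments") <- as.integer(n_excluded)
  attr(out, "n_ignored_segments") <- as.integer(n_ignored)
  class(out) <- c("malss_proteins", class(out))
  out
}

#' Construct a protein record table in memory
#'
#' @param accession Character vector of identifiers.
#' @param seq_length Integer vector of sequence lengths (amino acids).
#' @param segments List of integer vectors of segment lengths, one per protein.
#' @param kinds List of character vectors over \{"H","E"\}; defaults to all "H".
#' @param locations List of character vectors of subcellular-location labels
#'   (may be empty); defaults to none.
#' @return A `malss_proteins` tibble with derived columns `x` (segment count)
#'   and `y` (mean segment length).
#' @export
protein_records <- function(accession, seq_length, segments,
                            kinds = NULL, locations = NULL) {
  n <- length(accession)
  stopifnot(length(seq_length) == n, length(segments) == n)
  if (is.null(kinds)) kinds <- lapply(segments, function(s) rep("H", length(s)))
  if (is.null(locations)) locations <- rep(list(character(0)), n)
  for (i in seq_len(n)) {
    s <- segments[[i]]
    if (length(s) == 0) stop("protein ", accession[i], " has zero segments", call. = FALSE)
    if (any(s < 1)) stop("protein ", accession[i], " has a segment shorter than 1 AA", call. = FALSE)
    if (sum(s) > seq_length[i]) {
      stop("protein ", accession[i], ": segment lengths exceed sequence length", call. = FALSE)
    }
    if (!all(kinds[[i]] %in% c("H", "E"))) {
      stop("protein ", accession[i], ": segment kinds must be H or E", call. = FALSE)
    }
  }
  build_protein_tbl(accession, seq_length, locations,
                    lapply(segments, as.integer), kinds)
}

# Internal: parse one `segments` column string like "H:29,E:15,H:20".
# Returns list(lengths=, kinds=, ignored=<count of non-H/E tokens>) or
# signals an error mentioning the offending token.
parse_segment_string <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) {
    return(list(lengths = integer(0), kinds = character(0), ignored = 0L))
  }
  toks <- strsplit(trimws(s), ",", fixed = TRUE)[[1]]
  toks <- trimws(toks)
  parts <- strsplit(toks, ":", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) stop("malformed segment token '", toks[which(bad)[1]], "'", call. = FALSE)
  kind <- toupper(vapply(parts, `[[`, character(1), 1))
  len <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2)))
  if (anyNA(len) || any(len < 1)) {
    stop("segment token with non-positive or non-numeric length in '", s, "'", call. = FALSE)
  }
  known <- kind %in% c("H", "E", "T", "G", "B", "S", "I", "C")
  if (!all(known)) stop("unknown segment kind '", kind[!known][1], "'", call. = FALSE)
  keep <- kind %in% c("H", "E")
  list(lengths = len[keep], kinds = kind[keep], ignored = sum(!keep))
}

#' Read a protein table (TSV or JSON-lines)
#'
#' The TSV dialect has a header row and columns `accession`, `seq_length`,
#' `locations` (semicolon-separated labels, may be empty) and `segments`
#' (comma-separated `KIND:LENGTH` tokens with KIND in \{H,E\}; turn/coil
#' annotations such as T or G are ignored with a count). The JSON-lines
#' dialect carries one object per line with the same field names, `locations`
#' as an array of strings and `segments` as an array of `KIND:LENGTH` strings.
#'
#' Rows with zero H/E segments are excluded from the result; the number of
#' exclusions is available as `attr(x, "n_excluded_zero_segments")` and the
#' number of ignored non-H/E segment tokens as `attr(x, "n_ignored_segments")`.
#'
#' @param path File to read.
#' @param format `"tsv"` or `"jsonl"`; guessed from the file extension by
#'   default.
#' @param on_error `"stop"` (fail fast, reporting the row number) or `"skip"`
#'   (drop malformed rows, recording them in `attr(x, "n_skipped_rows")`).
#' @return A `malss_proteins` tibble (see [protein_records()]).
#' @export
read_protein_table <- function(path, format = c("auto", "tsv", "jsonl"),
                               on_error = c("stop", "skip")) {
  format <- match.arg(format)
  on_error <- match.arg(on_error)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "tsv"
  }
  if (format == "tsv") {
    raw <- utils::read.delim(path, sep = "\t", colClasses = "character",
                             na.strings = NULL, quote = "", check.names = FALSE)
    need <- c("accession", "seq_length", "locations", "segments")
    if (!all(need %in% names(raw))) {
      stop("protein table must have columns ", paste(need, collapse = ", "), call. = FALSE)
    }
    rows <- lapply(seq_len(nrow(raw)), function(i) {
      list(accession = raw$accession[i],
           seq_length = raw$seq_length[i],
           locations = raw$locations[i],
           segments = raw$segments[i])
    })
    loc_parse <- function(s) {
      if (is.na(s) || !nzchar(trimws(s))) character(0) else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    }
    seg_parse <- parse_segment_string
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
    loc_parse <- function(v) as.character(v)
    seg_parse <- function(v) {
      if (length(v) == 0) return(list(lengths = integer(0), kinds = character(0), ignored = 0L))
      parse_segment_string(paste(v, collapse = ","))
    }
  }

  acc <- character(0); sl <- integer(0)
  locs <- list(); segl <- list(); segk <- list()
  n_excluded <- 0L; n_ignored <- 0L; n_skipped <- 0L
  for (i in seq_along(rows)) {
    row <- rows[[i]]
    parsed <- tryCatch({
      L <- suppressWarnings(as.integer(row$seq_length))
      if (is.na(L) || L < 1) stop("invalid seq_length '", row$seq_length, "'", call. = FALSE)
      sg <- seg_parse(row$segments)
      if (sum(sg$lengths) > L) stop("segment lengths exceed sequence length", call. = FALSE)
      list(acc = as.character(row$accession), L = L,
           loc = loc_parse(row$locations), sg = sg)
    }, error = function(e) e)
    if (inherits(parsed, "error")) {
      if (on_error == "stop") {
        stop("row ", i, ": ", conditionMessage(parsed), call. = FALSE)
      }
      n_skipped <- n_skipped + 1L
      next
    }
    n_ignored <- n_ignored + parsed$sg$ignored
    if (length(parsed$sg$lengths) == 0) {
      n_excluded <- n_excluded + 1L
      next
    }
    acc <- c(acc, parsed$acc); sl <- c(sl, parsed$L)
    locs <- c(locs, list(parsed$loc))
    segl <- c(segl, list(parsed$sg$lengths))
    segk <- c(segk, list(parsed$sg$kinds))
  }
  out <- build_protein_tbl(acc, sl, locs, segl, segk, n_excluded, n_ignored)
  attr(out, "n_skipped_rows") <- n_skipped
  out
}

#' Write a protein table
#'
#' Emits the same TSV / JSON-lines dialects that [read_protein_table()]
#' consumes, so that write-then-read is the identity on valid records.
#'
#' @param proteins A `malss_proteins` tibble.
#' @param path Output file.
#' @param format `"tsv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(proteins, path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  seg_str <- mapply(function(k, l) paste0(k, ":", l, collapse = ","),
                    proteins$seg_kinds, proteins$seg_lengths)
  if (format == "tsv") {
    df <- data.frame(
      accession = proteins$accession,
      seq_length = proteins$seq_length,
      locations = vapply(proteins$locations, paste, character(1), collapse = ";"),
      segments = seg_str,
      stringsAsFactors = FALSE
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- vapply(seq_len(nrow(proteins)), function(i) {
      jsonlite::toJSON(list(
        accession = jsonlite::unbox(proteins$accession[i]),
        seq_length = jsonlite::unbox(proteins$seq_length[i]),
        locations = proteins$locations[[i]],
        segments = paste0(proteins$seg_kinds[[i]], ":", proteins$seg_lengths[[i]])
      ))
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read / write a coverage table
#'
#' TSV with header columns `accession`, `seq_length`, `observed_start`,
#' `observed_end` (1-based inclusive residue coordinates of the single
#' continuously observed interval).
#'
#' @param path File path.
#' @return `read_coverage_table()`: a tibble of coverage records.
#' @export
read_coverage_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE)
  need <- c("accession", "seq_length", "observed_start", "observed_end")
  if (!all(need %in% names(df))) {
    stop("coverage table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(df[need])
  out$accession <- as.character(out$accession)
  passes_coverage(out)  # validates invariants
  out
}

#' @rdname read_coverage_table
#' @param coverage A coverage tibble.
#' @export
write_coverage_table <- function(coverage, path) {
  utils::write.table(coverage[, c("accession", "seq_length", "observed_start", "observed_end")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply the coverage filter to a protein table
#'
#' @param proteins A `malss_proteins` tibble.
#' @param coverage A coverage tibble; proteins without a coverage record are
#'   dropped.
#' @return The admitted subset, with attributes `n_input`, `n_admitted`.
#' @export
filter_by_coverage <- function(proteins, coverage) {
  ok <- coverage$accession[passes_coverage(coverage)]
  out <- proteins[proteins$accession %in% ok, , drop = FALSE]
  attr(out, "n_input") <- nrow(proteins)
  attr(out, "n_admitted") <- nrow(out)
  out
}
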