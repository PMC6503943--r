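IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Construct a set of sequence records
#'
#' Records are kept in a tibble with one row per read: `id` (whitespace-free
#' token), `desc` (free text), `seq` (uppercase IUPAC DNA) and `qual`, a
#' list-column of integer Phred scores (or `NULL` entries for FASTA-style
#' records).  All other longamp functions consume and produce this shape.
#'
#' @param id character vector of record identifiers (no whitespace, non-empty).
#' @param seq character vector of DNA sequences; lowercase is uppercased and
#'   `U` normalized to `T` (case and uracil carry no meaning on input).
#' @param qual optional list of integer Phred score vectors, one per record,
#'   each exactly as long as its sequence; or `NULL` for no qualities.
#' @param desc character vector of free-text descriptions.
#' @return a tibble of class `seq_records`.
#' @examples
#' seq_records("r1", "ACGT")
#' seq_records("r1", "acgu", qual = list(c(30L, 30L, 30L, 30L)))
#' @export
seq_records <- function(id, seq, qual = NULL, desc = "") {
  id <- as.character(id)
  seq <- normalize_seq(seq)
  n <- length(id)
  stopifnot(length(seq) == n)
  if (is.null(qual)) qual <- rep(list(NULL), n)
  desc <- rep_len(as.character(desc), n)
  x <- tibble(id = id, desc = desc, seq = seq, qual = qual)
  validate_records(x)
  class(x) <- c("seq_records", class(x))
  x
}

normalize_seq <- function(seq) {
  chartr("U", "T", toupper(as.character(seq)))
}

validate_records <- function(x, context = "record") {
  if (any(!nzchar(x$id)) || anyNA(x$id))
    stop("record ids must be non-empty")
  if (any(grepl("[[:space:]]", x$id)))
    stop("record ids must not contain whitespace")
  bad <- grepl(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")), x$seq)
  if (any(bad))
    stop(sprintf("%s '%s': sequence contains non-IUPAC characters",
                 context, x$id[which(bad)[1]]))
  for (i in seq_len(nrow(x))) {
    q <- x$qual[[i]]
    if (is.null(q)) next
    if (length(q) != nchar(x$seq[i]))
      stop(sprintf("%s '%s': %d quality scores for %d bases",
                   context, x$id[i], length(q), nchar(x$seq[i])))
    if (any(q < 0)) stop(sprintf("%s '%s': negative Phred score", context, x$id[i]))
  }
  invisible(x)
}

decode_phred <- function(s) utf8ToInt(s) - 33L

encode_phred <- function(q) intToUtf8(pmin(q, 93L) + 33L)

#' Read sequences from FASTA or FASTQ
#'
#' Parsing is delegated to Biostrings; qualities are decoded as Phred+33.
#' Wrapped FASTA bodies are joined; lowercase input is uppercased and `U`
#' normalized to `T`.
#'
#' @param path file path (plain or gzipped).
#' @param format `"auto"` (detect from the first character: `>` FASTA,
#'   `@` FASTQ), `"fasta"` or `"fastq"`.
#' @return a `seq_records` tibble, in file order.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    con <- gzfile(path, "rt")
    first_line <- readLines(con, n = 1L, warn = FALSE)
    close(con)
    if (length(first_line) == 0)
      return(seq_records(character(), character()))
    first <- substr(first_line, 1L, 1L)
    if (identical(first, ">")) format <- "fasta"
    else if (identical(first, "@")) format <- "fastq"
    else stop("cannot auto-detect format of ", path,
              " (first character is neither '>' nor '@')")
  }
  if (format == "fasta") {
    ss <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                   error = function(e) stop("malformed FASTA in ", path, ": ",
                                            conditionMessage(e), call. = FALSE))
    nm <- names(ss)
    id <- sub("[[:space:]].*$", "", nm)
    desc <- ifelse(grepl("[[:space:]]", nm),
                   sub("^[^[:space:]]+[[:space:]]+", "", nm), "")
    recs <- seq_records(id, as.character(ss), desc = desc)
  } else {
    ss <- tryCatch(
      Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
      error = function(e) fastq_diagnose(path, conditionMessage(e)))
    nm <- names(ss)
    id <- sub("[[:space:]].*$", "", nm)
    desc <- ifelse(grepl("[[:space:]]", nm),
                   sub("^[^[:space:]]+[[:space:]]+", "", nm), "")
    seqs <- as.character(ss)
    quals <- tryCatch({
      q <- as.character(S4Vectors::mcols(ss)$qualities)
      bad <- which(nchar(q, type = "bytes") != nchar(seqs, type = "bytes"))
      if (length(bad))
        stop(sprintf("%d quality characters for %d bases",
                     nchar(q[bad[1]], type = "bytes"), nchar(seqs[bad[1]])))
      lapply(q, decode_phred)
    }, error = function(e) fastq_diagnose(path, conditionMessage(e)))
    recs <- seq_records(id, seqs, qual = quals, desc = desc)
  }
  recs
}

# On a Biostrings FASTQ parse failure, scan the file to name the offending
# record before giving up.
fastq_diagnose <- function(path, msg) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  while (i + 3L <= length(lines)) {
    if (nchar(lines[i + 1L]) != nchar(lines[i + 3L]))
      stop(sprintf(
        "malformed FASTQ record '%s': %d quality characters for %d bases",
        sub("^@", "", sub("[[:space:]].*$", "", lines[i])),
        nchar(lines[i + 3L]), nchar(lines[i + 1L])), call. = FALSE)
    i <- i + 4L
  }
  stop("malformed FASTQ in ", path, ": ", msg, call. = FALSE)
}

#' Write sequences to FASTA or FASTQ
#'
#' FASTA bodies are wrapped at 80 columns.  `lowercase_mask` lowercases the
#' given 0-based half-open intervals of each record in FASTA output (used to
#' mark index/primer regions); it is rejected for FASTQ, where case is not
#' representable.
#'
#' @param records a `seq_records` tibble.
#' @param path output file path.
#' @param format `"fasta"` or `"fastq"`; FASTQ requires qualities on every
#'   record.
#' @param lowercase_mask optional list (one element per record) of two-column
#'   matrices `cbind(start, end)` of 0-based half-open intervals to lowercase,
#'   or `NULL` entries for no masking.
#' @return the number of records written, invisibly.
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq"),
                            lowercase_mask = NULL) {
  format <- match.arg(format)
  n <- nrow(records)
  if (n == 0) {
    file.create(path)
    return(invisible(0L))
  }
  nm <- ifelse(nzchar(records$desc), paste(records$id, records$desc), records$id)
  if (format == "fastq") {
    if (!is.null(lowercase_mask))
      stop("lowercase masking is not representable in FASTQ")
    noq <- vapply(records$qual, is.null, logical(1))
    if (any(noq))
      stop("fastq output requires quality on every record (missing for '",
           records$id[which(noq)[1]], "')")
    lines <- character(4L * n)
    lines[seq(1, by = 4, length.out = n)] <- paste0("@", nm)
    lines[seq(2, by = 4, length.out = n)] <- records$seq
    lines[seq(3, by = 4, length.out = n)] <- "+"
    lines[seq(4, by = 4, length.out = n)] <-
      vapply(records$qual, encode_phred, character(1))
    writeLines(lines, path)
  } else {
    seqs <- records$seq
    if (!is.null(lowercase_mask)) {
      stopifnot(length(lowercase_mask) == n)
      for (i in seq_len(n)) {
        iv <- lowercase_mask[[i]]
        if (is.null(iv)) next
        iv <- matrix(as.integer(iv), ncol = 2)
        ch <- strsplit(seqs[i], "")[[1]]
        for (r in seq_len(nrow(iv))) {
          s <- max(iv[r, 1] + 1L, 1L)
          e <- min(iv[r, 2], length(ch))
          if (s <= e) ch[s:e] <- tolower(ch[s:e])
        }
        seqs[i] <- paste(ch, collapse = "")
      }
    }
    ss <- Biostrings::BStringSet(seqs)
    names(ss) <- nm
    Biostrings::writeXStringSet(ss, path, format = "fasta", width = 80L)
  }
  invisible(n)
}

#' Parse a tab-delimited barcode table
#'
#' Each data row describes one sample's dual index/primer quadruple:
#' `sample_name`, `fwd_index`, `fwd_primer`, `rev_index`, `rev_primer` (in
#' that order).  Lines starting with `#` are comments; extra columns beyond
#' the fifth are ignored with a warning.  Indexes must be plain ACGT;
#' primers may carry IUPAC degeneracies.
#'
#' @param path path to the TSV barcode file.
#' @return a tibble of sample specs (one row per sample).
#' @export
parse_barcode_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0)
    return(tibble(sample_name = character(), fwd_index = character(),
                  fwd_primer = character(), rev_index = character(),
                  rev_primer = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 5))
    stop(sprintf("barcode table row %d has %d columns; 5 required",
                 which(ncol < 5)[1], min(ncol)))
  if (any(ncol > 5))
    warning("barcode table has rows with >5 columns; extra columns ignored")
  m <- t(vapply(parts, function(p) p[1:5], character(5)))
  spec <- tibble(sample_name = trimws(m[, 1]),
                 fwd_index = normalize_seq(trimws(m[, 2])),
                 fwd_primer = normalize_seq(trimws(m[, 3])),
                 rev_index = normalize_seq(trimws(m[, 4])),
                 rev_primer = normalize_seq(trimws(m[, 5])))
  validate_sample_specs(spec)
  spec
}

validate_sample_specs <- function(spec) {
  if (anyDuplicated(spec$sample_name))
    stop("duplicate sample name: ",
         spec$sample_name[duplicated(spec$sample_name)][1])
  pair <- paste(spec$fwd_index, spec$rev_index)
  if (anyDuplicated(pair))
    stop("duplicate (fwd_index, rev_index) pair for samples: ",
         paste(spec$sample_name[pair %in% pair[duplicated(pair)]],
               collapse = ", "))
  for (col in c("fwd_index", "rev_index")) {
    bad <- grepl("[^ACGT]", spec[[col]])
    if (any(bad))
      stop(sprintf("sample '%s': %s contains non-ACGT characters (%s)",
                   spec$sample_name[which(bad)[1]], col,
                   spec[[col]][which(bad)[1]]))
  }
  for (col in c("fwd_primer", "rev_primer")) {
    bad <- grepl(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")),
                 spec[[col]])
    if (any(bad))
      stop(sprintf("sample '%s': %s contains non-IUPAC characters",
                   spec$sample_name[which(bad)[1]], col))
  }
  if (any(!nzchar(spec$fwd_index)) || any(!nzchar(spec$rev_index)))
    stop("empty index")
  invisible(spec)
}

#' Write a barcode table
#'
#' Inverse of [parse_barcode_table()]; writes the five-column TSV consumed by
#' the demultiplexer.
#'
#' @param spec a sample-spec tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_barcode_table <- function(spec, path) {
  validate_sample_specs(spec)
  writeLines(c("#sample_name\tfwd_index\tfwd_primer\trev_index\trev_primer",
               sprintf("%s\t%s\t%s\t%s\t%s", spec$sample_name, spec$fwd_index,
                       spec$fwd_primer, spec$rev_index, spec$rev_primer)),
             path)
  invisible(path)
}
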