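#' Construct a locus alignment
#'
#' The in-memory alignment container used throughout the package: a character
#' matrix of aligned residues (taxa in rows, sites in columns) plus the
#' alphabet and any named column partitions. Normally produced by
#' [read_alignment()] or [simulate_locus()]; the constructor is exported so
#' alignments can be built programmatically.
#'
#' @param seqs named character vector of aligned sequences (one string per
#'   taxon) or a character matrix with taxa as rownames.
#' @param locus locus label.
#' @param alphabet `"DNA"`, `"PROTEIN"`, or `NULL` to auto-detect (at least
#'   80 percent of non-gap characters in `A,C,G,T,U,N` means DNA).
#' @param partitions optional named list of 1-based column index vectors
#'   (NEXUS charsets). Overlapping partitions are allowed with a warning.
#' @return an object of class `pi_alignment` with fields `locus`, `taxa`,
#'   `seq` (character matrix), `alphabet`, `partitions`.
#' @examples
#' aln <- alignment(c(human = "ACGT", mouse = "ACGA"), locus = "toy")
#' aln$alphabet
#' @export
alignment <- function(seqs, locus = "locus", alphabet = NULL, partitions = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("sequences must be named by taxon", call. = FALSE)
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1) {
      bad <- names(seqs)[which(lens != lens[1])[1]]
      stop(sprintf("alignment malformed: sequence length for taxon '%s' (%d) differs from '%s' (%d)",
                   bad, lens[[bad]], names(seqs)[1], lens[1]), call. = FALSE)
    }
    mat <- do.call(rbind, strsplit(unname(seqs), ""))
    rownames(mat) <- names(seqs)
  }
  validate_alignment(mat, locus, alphabet, partitions)
}

validate_alignment <- function(mat, locus, alphabet = NULL, partitions = NULL) {
  taxa <- rownames(mat)
  if (is.null(taxa) || any(!nzchar(taxa)))
    stop("taxon labels must be non-empty", call. = FALSE)
  if (anyDuplicated(taxa))
    stop(sprintf("duplicate taxon label: '%s'", taxa[duplicated(taxa)][1]),
         call. = FALSE)
  if (ncol(mat) < 1) stop("alignment has zero columns", call. = FALSE)
  mat <- toupper(mat)
  if (is.null(alphabet)) alphabet <- detect_alphabet(mat)
  alphabet <- match.arg(alphabet, c("DNA", "PROTEIN"))
  if (alphabet == "DNA") mat[mat == "U"] <- "T"
  allowed <- if (alphabet == "DNA") DNA_ALLOWED else AA_ALLOWED
  bad <- setdiff(unique(as.vector(mat)), allowed)
  if (length(bad))
    stop(sprintf("invalid %s character(s): %s", alphabet,
                 paste(shQuote(bad), collapse = ", ")), call. = FALSE)
  partitions <- check_partitions(partitions, ncol(mat))
  structure(list(locus = locus, taxa = taxa, seq = mat,
                 alphabet = alphabet, partitions = partitions),
            class = "pi_alignment")
}

detect_alphabet <- function(mat) {
  chars <- as.vector(mat)
  chars <- chars[!chars %in% c("-", "?", ".")]
  if (!length(chars)) return("DNA")
  frac <- mean(chars %in% c("A", "C", "G", "T", "U", "N"))
  if (frac >= 0.8) "DNA" else "PROTEIN"
}

check_partitions <- function(partitions, len) {
  if (is.null(partitions) || !length(partitions)) return(NULL)
  if (is.null(names(partitions)) || any(!nzchar(names(partitions))))
    stop("partitions must be named", call. = FALSE)
  partitions <- lapply(partitions, function(idx) {
    idx <- as.integer(idx)
    if (any(idx < 1L | idx > len))
      stop(sprintf("partition column index out of range [1, %d]", len),
           call. = FALSE)
    idx
  })
  all_idx <- unlist(partitions)
  if (anyDuplicated(all_idx))
    warning("partitions overlap; overlapping columns are profiled in each partition",
            call. = FALSE)
  partitions
}

#' @export
print.pi_alignment <- function(x, ...) {
  cat(sprintf("<pi_alignment '%s': %d taxa x %d sites (%s)%s>\n",
              x$locus, length(x$taxa), ncol(x$seq), x$alphabet,
              if (length(x$partitions))
                sprintf(", %d partitions", length(x$partitions)) else ""))
  invisible(x)
}

#' Read a sequence alignment
#'
#' Reads DNA or amino-acid alignments in FASTA, Phylip (sequential or
#' interleaved, strict or relaxed names) or NEXUS format. The format is
#' sniffed from the first non-blank line unless given: a leading `>` means
#' FASTA, `#NEXUS` (case-insensitive) means NEXUS, and a leading integer pair
#' means Phylip. NEXUS `charset` statements (including range syntax `a-b` and
#' codon-step syntax `a-b\\3`) populate the partition map.
#'
#' @param path path to the alignment file.
#' @param format one of `"fasta"`, `"phylip"`, `"nexus"`, or `NULL` to sniff.
#' @param alphabet `"DNA"`, `"PROTEIN"`, or `NULL` to auto-detect.
#' @param locus locus label; defaults to the file name without extension.
#' @return a `pi_alignment` (see [alignment()]).
#' @export
read_alignment <- function(path, format = NULL, alphabet = NULL, locus = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(locus))
    locus <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(format)) format <- sniff_alignment_format(path)
  format <- match.arg(tolower(format), c("fasta", "phylip", "nexus"))
  parsed <- switch(format,
    fasta = parse_fasta(path),
    phylip = parse_phylip(path),
    nexus = parse_nexus_matrix(path)
  )
  validate_alignment(parsed$mat, locus, alphabet, parsed$partitions)
}

sniff_alignment_format <- function(path) {
  lines <- readLines(path, n = 50, warn = FALSE)
  first <- lines[nzchar(trimws(lines))][1]
  if (is.na(first))
    stop(sprintf("format error in %s, line 1: file is empty", path), call. = FALSE)
  if (startsWith(first, ">")) return("fasta")
  if (grepl("^#nexus", trimws(first), ignore.case = TRUE)) return("nexus")
  if (grepl("^\\s*\\d+\\s+\\d+\\s*$", first)) return("phylip")
  stop(sprintf("format error in %s, line %d: cannot identify format from '%s'",
               path, which(lines == first)[1], substr(first, 1, 40)), call. = FALSE)
}

parse_fasta <- function(path) {
  recs <- tryCatch(Biostrings::readBStringSet(path), error = function(e)
    stop(sprintf("format error in %s: %s", path, conditionMessage(e)), call. = FALSE))
  if (!length(recs))
    stop(sprintf("format error in %s: no FASTA records", path), call. = FALSE)
  seqs <- as.character(recs)
  names(seqs) <- sub("\\s.*$", "", names(seqs))  # keep identifier up to first space
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    bad <- names(seqs)[which(lens != lens[1])[1]]
    stop(sprintf("alignment malformed in %s: sequence for taxon '%s' has length %d, expected %d",
                 path, bad, lens[[bad]], lens[1]), call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(mat) <- names(seqs)
  list(mat = mat, partitions = NULL)
}

# Phylip, both dialects: relaxed (whitespace-delimited names of any length)
# and strict (names in the first 10 columns, possibly abutting the sequence).
# Sequences may wrap over lines (sequential) or cycle in blocks (interleaved);
# continuation lines carry no names in either dialect.
parse_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_i <- which(nzchar(trimws(lines)))[1]
  hdr <- strsplit(trimws(lines[hdr_i]), "\\s+")[[1]]
  if (length(hdr) < 2 || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
    stop(sprintf("format error in %s, line %d: expected 'ntax nchar' header",
                 path, hdr_i), call. = FALSE)
  ntax <- as.integer(hdr[1]); nchar_exp <- as.integer(hdr[2])
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < ntax)
    stop(sprintf("format error in %s: %d taxa declared but only %d data lines",
                 path, ntax, length(body)), call. = FALSE)
  seqs <- phylip_read_body(body, ntax, nchar_exp, strict = FALSE)
  if (is.null(seqs)) seqs <- phylip_read_body(body, ntax, nchar_exp, strict = TRUE)
  if (is.null(seqs))
    stop(sprintf("alignment malformed in %s: sequence lengths do not match the declared %d columns",
                 path, nchar_exp), call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
  rownames(mat) <- names(seqs)
  list(mat = mat, partitions = NULL)
}

phylip_read_body <- function(body, ntax, nchar_exp, strict) {
  first <- body[seq_len(ntax)]
  if (strict) {
    names_ <- trimws(substr(first, 1, 10))
    seqs <- gsub("\\s+", "", substr(first, 11, nchar(first)))
  } else {
    toks <- strsplit(trimws(first), "\\s+")
    names_ <- vapply(toks, `[[`, character(1), 1)
    seqs <- vapply(toks, function(tk) paste(tk[-1], collapse = ""), character(1))
  }
  rest <- body[-seq_len(ntax)]
  i <- 0L
  for (ln in rest) {
    i <- i %% ntax + 1L
    seqs[i] <- paste0(seqs[i], gsub("\\s+", "", ln))
  }
  if (any(nchar(seqs) != nchar_exp) || any(!nzchar(names_))) return(NULL)
  stats::setNames(seqs, names_)
}

parse_nexus_matrix <- function(path) {
  dat <- tryCatch(ape::read.nexus.data(path), error = function(e)
    stop(sprintf("format error in %s: %s", path, conditionMessage(e)), call. = FALSE))
  lens <- lengths(dat)
  if (length(unique(lens)) > 1) {
    bad <- names(dat)[which(lens != lens[1])[1]]
    stop(sprintf("alignment malformed in %s: sequence for taxon '%s' has length %d, expected %d",
                 path, bad, lens[[bad]], lens[1]), call. = FALSE)
  }
  mat <- do.call(rbind, lapply(dat, toupper))
  rownames(mat) <- names(dat)
  list(mat = mat, partitions = parse_nexus_charsets(path, ncol(mat)))
}

# charset grammar: "charset NAME = TOKEN TOKEN ... ;" where TOKEN is
# "a", "a-b", "a-.", or "a-b\k" (every k-th column of [a, b]).
parse_nexus_charsets <- function(path, len) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", "", txt)  # strip NEXUS comments
  m <- gregexpr("(?i)charset\\s+([A-Za-z0-9_.+-]+)\\s*=\\s*([^;]+);", txt, perl = TRUE)
  hits <- regmatches(txt, m)[[1]]
  if (!length(hits)) return(NULL)
  out <- list()
  for (h in hits) {
    name <- sub("(?i)charset\\s+([A-Za-z0-9_.+-]+)\\s*=.*", "\\1", h, perl = TRUE)
    spec <- sub("(?i)charset\\s+[A-Za-z0-9_.+-]+\\s*=\\s*([^;]+);", "\\1", h, perl = TRUE)
    out[[name]] <- expand_charset(spec, len, name)
  }
  out
}

expand_charset <- function(spec, len, name = "charset") {
  tokens <- strsplit(trimws(spec), "\\s+")[[1]]
  idx <- integer(0)
  for (tk in tokens) {
    m <- regmatches(tk, regexec("^(\\d+)(?:-(\\d+|\\.))?(?:\\\\(\\d+))?$", tk))[[1]]
    if (!length(m))
      stop(sprintf("cannot parse charset token '%s' in charset %s", tk, name),
           call. = FALSE)
    a <- as.integer(m[2])
    b <- if (m[3] == "") a else if (m[3] == ".") len else as.integer(m[3])
    step <- if (m[4] == "") 1L else as.integer(m[4])
    if (b < a) stop(sprintf("charset range '%s' is empty", tk), call. = FALSE)
    idx <- c(idx, seq.int(a, b, by = step))
  }
  sort(unique(idx))
}

#' Split a partitioned alignment into pseudo-loci
#'
#' Each named partition (NEXUS charset) becomes its own single-locus
#' alignment, so partitions can be profiled and ranked as loci in their own
#' right.
#'
#' @param aln a `pi_alignment` with partitions.
#' @return a named list of `pi_alignment` objects, one per partition. An
#'   alignment without partitions is returned as a one-element list keyed by
#'   its locus name.
#' @export
split_partitions <- function(aln) {
  stopifnot(inherits(aln, "pi_alignment"))
  if (!length(aln$partitions)) return(stats::setNames(list(aln), aln$locus))
  lapply(stats::setNames(nm = names(aln$partitions)), function(nm) {
    idx <- aln$partitions[[nm]]
    sub <- aln$seq[, idx, drop = FALSE]
    validate_alignment(sub, nm, aln$alphabet, NULL)
  })
}
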