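#' Construct a phyletic pattern
#'
#' A phyletic pattern (phylogenetic profile) records presence (1) versus
#' absence (0) of binary characters across species: a 0/1 matrix whose rows
#' are taxa and whose columns are characters, equivalent to a gap-free binary
#' alignment. Only strictly binary data are supported; missing-data symbols
#' are rejected because silent imputation would change likelihoods.
#'
#' @param matrix integer/numeric matrix with entries in \{0, 1\}.
#' @param taxa character vector of unique, non-empty species names
#'   (defaults to rownames).
#' @param characters character vector of unique character identifiers
#'   (defaults to colnames, else \code{C0001}, \code{C0002}, ...).
#' @param annotations optional named character vector mapping character ids
#'   to free-text descriptions.
#' @return An object of class \code{phyletic_pattern} with components
#'   \code{matrix} (0/1 integer matrix), \code{taxa}, \code{characters} and
#'   \code{annotations}.
#' @examples
#' p <- phyletic_pattern(rbind(A = c(0, 1), B = c(1, 1)))
#' p$characters
#' @export
phyletic_pattern <- function(matrix, taxa = rownames(matrix),
                             characters = colnames(matrix),
                             annotations = NULL) {
  m <- as.matrix(matrix)
  if (is.null(taxa)) stop("taxa names are required")
  taxa <- as.character(taxa)
  if (is.null(characters)) {
    characters <- sprintf("C%04d", seq_len(ncol(m)))
  }
  characters <- as.character(characters)
  if (length(taxa) != nrow(m)) stop("number of taxa must equal number of rows")
  if (length(characters) != ncol(m)) {
    stop("number of character ids must equal number of columns")
  }
  if (ncol(m) < 1L) stop("no characters")
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon name: ", taxa[duplicated(taxa)][1L])
  }
  if (any(!nzchar(taxa))) stop("empty taxon name")
  if (anyDuplicated(characters)) {
    stop("duplicate character id: ", characters[duplicated(characters)][1L])
  }
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m == 0L | m == 1L)) {
    bad <- which(is.na(m) | !(m %in% c(0L, 1L)), arr.ind = TRUE)[1L, ]
    stop("binary characters only: entry for taxon '", taxa[bad[1L]],
         "' at character position ", bad[2L], " is not 0/1")
  }
  dimnames(m) <- list(taxa, characters)
  ann <- validate_annotations(annotations, characters)
  structure(list(matrix = m, taxa = taxa, characters = characters,
                 annotations = ann),
            class = "phyletic_pattern")
}

validate_annotations <- function(annotations, characters) {
  if (is.null(annotations) || length(annotations) == 0L) {
    return(NULL)
  }
  ann <- unlist(annotations)
  storage.mode(ann) <- "character"
  if (is.null(names(ann))) stop("annotations must be named by character id")
  extra <- setdiff(names(ann), characters)
  if (length(extra)) {
    warning("annotations for unknown characters ignored: ",
            paste(utils::head(extra, 5L), collapse = ", "))
    ann <- ann[names(ann) %in% characters]
  }
  if (length(ann) == 0L) NULL else ann
}

#' @export
print.phyletic_pattern <- function(x, ...) {
  cat("Phyletic pattern:", length(x$taxa), "taxa x",
      length(x$characters), "characters\n")
  cat(sprintf("  presence fraction: %.3f\n", mean(x$matrix)))
  if (!is.null(x$annotations)) {
    cat("  annotated characters:", length(x$annotations), "\n")
  }
  invisible(x)
}

#' Read a phyletic pattern from file
#'
#' Two dialects are supported. \code{fasta01}: FASTA records whose sequences
#' are strings over the alphabet \{0, 1\}, one record per taxon, all of equal
#' length. \code{tsv}: a tab-separated matrix whose header row holds
#' character ids and whose first column holds taxon names (set
#' \code{transpose = TRUE} for the rows-are-characters dialect).
#'
#' Any symbol outside \{0, 1\} (including missing-data codes such as
#' \code{?}) is a fatal error naming the offending taxon and position.
#'
#' @param path file path.
#' @param format \code{"fasta01"} or \code{"tsv"}.
#' @param transpose for \code{tsv}, read columns as taxa and rows as
#'   characters.
#' @return A \code{\link{phyletic_pattern}}.
#' @export
read_pattern <- function(path, format = c("fasta01", "tsv"),
                         transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta01") {
    read_pattern_fasta01(path)
  } else {
    read_pattern_tsv(path, transpose = transpose)
  }
}

read_pattern_fasta01 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[[1L]], ">")) {
    stop("not a FASTA file: ", path)
  }
  hdr <- grepl("^>", lines)
  rec <- cumsum(hdr)
  taxa <- trimws(sub("^>", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) paste(trimws(x), collapse = ""), character(1L))
  if (length(seqs) != length(taxa) || any(!nzchar(seqs))) {
    stop("FASTA record with empty sequence")
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("ragged rows: sequences differ in length (",
         paste(range(lens), collapse = "-"), ")")
  }
  chars <- strsplit(seqs, "", fixed = TRUE)
  for (i in seq_along(chars)) {
    bad <- which(!(chars[[i]] %in% c("0", "1")))
    if (length(bad)) {
      stop("binary characters only: taxon '", taxa[i], "' has symbol '",
           chars[[i]][bad[1L]], "' at position ", bad[1L])
    }
  }
  m <- do.call(rbind, lapply(chars, function(x) as.integer(x == "1")))
  rownames(m) <- taxa
  phyletic_pattern(m, taxa = taxa)
}

read_pattern_tsv <- function(path, transpose = FALSE) {
  tab <- utils::read.delim(path, header = TRUE, row.names = 1L,
                           check.names = FALSE, colClasses = "character")
  m <- as.matrix(tab)
  suppressWarnings(storage.mode(m) <- "integer")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("binary characters only: non-numeric entry at row '",
         rownames(tab)[bad[1L]], "', column ", bad[2L])
  }
  if (transpose) m <- t(m)
  phyletic_pattern(m)
}

#' Write a phyletic pattern to file
#'
#' Output is re-readable by \code{\link{read_pattern}}; a read of a write is
#' the identity on valid patterns. FASTA sequences are wrapped at 60
#' characters; files use Unix newlines.
#'
#' @param p a \code{\link{phyletic_pattern}}.
#' @param path output path.
#' @param format \code{"fasta01"} or \code{"tsv"}.
#' @export
write_pattern <- function(p, path, format = c("fasta01", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(p, "phyletic_pattern"))
  if (length(p$characters) == 0L) stop("no characters")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (format == "fasta01") {
    for (i in seq_along(p$taxa)) {
      seq <- paste(p$matrix[i, ], collapse = "")
      wrapped <- substring(seq, seq(1L, nchar(seq), 60L),
                           pmin(seq(60L, nchar(seq) + 59L, 60L), nchar(seq)))
      writeLines(c(paste0(">", p$taxa[i]), wrapped), con, sep = "\n")
    }
  } else {
    writeLines(paste(c("taxon", p$characters), collapse = "\t"), con, sep = "\n")
    for (i in seq_along(p$taxa)) {
      writeLines(paste(c(p$taxa[i], p$matrix[i, ]), collapse = "\t"),
                 con, sep = "\n")
    }
  }
  invisible(path)
}

#' Read a character annotation table
#'
#' Two-column tab-separated file: character id, free-text description.
#' Malformed lines are skipped with a warning; on duplicated ids the first
#' entry wins with a warning.
#'
#' @param path file path.
#' @return named character vector (id -> description); empty vector for an
#'   empty file.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(structure(character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 2L
  if (any(!ok)) {
    warning(sum(!ok), " malformed annotation line(s) skipped")
    parts <- parts[ok]
  }
  ids <- vapply(parts, `[[`, character(1L), 1L)
  desc <- vapply(parts, function(x) paste(x[-1L], collapse = "\t"), character(1L))
  dup <- duplicated(ids)
  if (any(dup)) {
    warning("duplicated annotation id(s), first kept: ",
            paste(unique(ids[dup]), collapse = ", "))
    desc <- desc[!dup]
    ids <- ids[!dup]
  }
  stats::setNames(desc, ids)
}
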