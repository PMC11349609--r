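#' @importFrom stats aov as.dist complete.cases cor dist hclust kruskal.test
#'   lm.fit reorder rnorm runif sd setNames bartlett.test TukeyHSD
#' @importFrom utils read.csv write.csv read.delim write.table
NULL

IUPAC_CODES <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-", "?")

#' Construct a multiple-sequence alignment object
#'
#' An `alignment` holds equal-length IUPAC DNA sequences with unique ids, the
#' shared column count, and a locus name. Sequences are stored upper-case;
#' gaps (`-`) and unknowns (`?`, `N`, ambiguity codes) are retained verbatim.
#'
#' @param seqs named character vector of sequences (names are record ids).
#' @param locus_name label for the locus (e.g. `"cytb"`).
#' @return object of class `alignment` with elements `locus_name`, `ids`,
#'   `seqs` (named upper-case character vector) and `length` (columns).
#' @export
alignment <- function(seqs, locus_name = "locus") {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(trimws(ids))))
    stop("every sequence must carry a non-empty id")
  ids <- trimws(ids)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(gsub("[[:space:]]", "", seqs))
  lens <- nchar(seqs)
  if (length(seqs) < 1L || any(lens < 1L)) stop("alignment must have >= 1 column")
  if (length(unique(lens)) > 1L) {
    bad <- ids[lens != lens[1L]][1L]
    stop("ragged alignment: sequence '", bad, "' has length ", nchar(seqs[ids == bad]),
         ", expected ", lens[1L])
  }
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% IUPAC_CODES)
    if (length(bad))
      stop("illegal character '", chars[bad[1L]], "' in sequence '", ids[i],
           "' at position ", bad[1L])
  }
  names(seqs) <- ids
  structure(list(locus_name = locus_name, ids = ids, seqs = seqs,
                 length = unname(lens[1L])),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("<alignment> locus:", x$locus_name, "|", length(x$ids), "records x",
      x$length, "columns\n")
  invisible(x)
}

#' Alignment as a character matrix (records x columns)
#' @param aln an `alignment`.
#' @return character matrix with record ids as row names.
#' @export
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

#' Read a FASTA alignment
#'
#' Parses a multi-record FASTA file (wrapped or unwrapped) into a validated
#' [alignment()]. Case is normalised to upper; `-` and `?` are kept.
#'
#' @param path path to a FASTA file.
#' @param locus_name locus label stored on the alignment.
#' @return an `alignment`.
#' @export
read_fasta_alignment <- function(path, locus_name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (!length(recs)) stop("no FASTA records in ", path)
  seqs <- vapply(recs, function(r) as.character(r)[1L], character(1))
  names(seqs) <- vapply(recs, function(r) attr(r, "name"), character(1))
  alignment(seqs, locus_name = locus_name)
}

#' Write an alignment to FASTA
#' @param aln an `alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqinr::write.fasta(as.list(aln$seqs), names = aln$ids, file.out = path,
                      nbchar = 70)
  invisible(path)
}

#' Read a specimen/sequence group map
#'
#' Reads a delimited table (TSV or CSV, sniffed from the header line) with at
#' least `id` and `group` columns; optional `population` and `sex` columns and
#' any further columns are preserved.
#'
#' @param path path to the table.
#' @return a `group_map`: data frame with trimmed character `id`, `group`,
#'   plus any extra columns.
#' @export
read_group_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  group_map(df)
}

#' Construct a group map from a data frame
#' @param df data frame with columns `id` and `group` (others kept).
#' @return a `group_map` data frame.
#' @export
group_map <- function(df) {
  need <- c("id", "group")
  if (!all(need %in% names(df)))
    stop("group map needs columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  df$id <- trimws(as.character(df$id))
  df$group <- trimws(as.character(df$group))
  if (any(!nzchar(df$id))) stop("empty id in group map")
  if (anyDuplicated(df$id))
    stop("duplicate ids in group map: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  missing_grp <- df$id[is.na(df$group) | !nzchar(df$group)]
  if (length(missing_grp))
    stop("missing group label for: ", paste(missing_grp, collapse = ", "))
  class(df) <- c("group_map", "data.frame")
  df
}

#' Look up group labels for a set of ids
#' @param groups a `group_map`.
#' @param ids character vector of ids.
#' @return character vector of group labels, same order as `ids`.
#' @export
group_of <- function(groups, ids) {
  ids <- trimws(ids)
  idx <- match(ids, groups$id)
  if (anyNA(idx)) stop("ids not in group map: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  groups$group[idx]
}

#' Read / write Newick trees
#'
#' Thin validated wrappers around ape's Newick reader and writer. Trees are
#' `phylo` objects throughout the package; a rooted tree has a bifurcating
#' root.
#'
#' @param path file path.
#' @return `read_newick`: a `phylo`. `write_newick`: `path`, invisibly.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close)
    stop("unbalanced parentheses in Newick (", n_open, " '(' vs ",
         n_close, " ')')")
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels in tree")
  tr
}

#' @rdname read_newick
#' @param tree a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a morphometric measurement table
#'
#' CSV with leading columns `id`, `group` and optionally `sex`, followed by
#' named measurement columns in mm; empty cells are missing.
#'
#' @param path CSV path.
#' @return a `morpho_table`: data frame (`id`, `group`, optional `sex`,
#'   numeric measurement columns with NAs for missing).
#' @export
read_morpho_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  morpho_table(df)
}

#' Validate a morphometric table
#' @param df data frame with `id`, `group`, optional `sex`, then measurements.
#' @return a `morpho_table` data frame.
#' @export
morpho_table <- function(df) {
  if (!all(c("id", "group") %in% names(df)))
    stop("morphometric table needs 'id' and 'group' columns")
  df$id <- trimws(as.character(df$id))
  if (anyDuplicated(df$id)) stop("duplicate specimen ids")
  meas <- measurement_names(df)
  if (!length(meas)) stop("no measurement columns found")
  for (v in meas) {
    df[[v]] <- suppressWarnings(as.numeric(df[[v]]))
    bad <- !is.na(df[[v]]) & df[[v]] <= 0
    if (any(bad))
      stop("non-positive measurement in '", v, "' for ",
           paste(df$id[bad], collapse = ", "))
  }
  class(df) <- c("morpho_table", "data.frame")
  df
}

#' Names of the measurement columns of a morpho table
#' @param df a `morpho_table` (or compatible data frame).
#' @return character vector of measurement column names.
#' @export
measurement_names <- function(df) {
  setdiff(names(df), c("id", "group", "sex", "population"))
}

#' Measurement matrix of a morpho table
#' @param df a `morpho_table`.
#' @return numeric matrix, specimens x measurements, row names = ids.
#' @export
measurement_matrix <- function(df) {
  m <- as.matrix(df[, measurement_names(df), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$id
  m
}
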