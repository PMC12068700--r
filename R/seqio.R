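# Alignment / tree / trait-table IO and cross-file harmonization.

#' Normalize taxon labels
#'
#' Whitespace runs become single underscores so that FASTA headers and newick
#' labels (which quote spaces differently) match by exact string comparison.
#'
#' @param x character vector of labels.
#' @return character vector of normalized labels.
#' @export
normalize_taxon <- function(x) {
  gsub("[[:space:]]+", "_", trimws(x))
}

#' Construct a validated protein alignment
#'
#' @param rows character matrix (sequences in rows, columns are alignment
#'   positions) with symbols from [RES_ALPHABET].
#' @param ids unique sequence identifiers, one per row.
#' @param provenance free-text metadata (e.g. upstream aligner settings).
#' @return an object of class `res_alignment` with elements `ids`, `rows`
#'   (the symbol matrix, rownames = ids), and `provenance`.
#' @export
new_alignment <- function(rows, ids = rownames(rows), provenance = character()) {
  if (!is.matrix(rows) || !is.character(rows))
    stop("`rows` must be a character matrix")
  if (is.null(ids)) stop("sequence ids are required")
  ids <- normalize_taxon(as.character(ids))
  if (nrow(rows) != length(ids))
    stop("number of ids does not match number of rows")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (nrow(rows) < 2) stop("alignment needs at least 2 sequences")
  if (ncol(rows) < 1) stop("alignment needs at least 1 column")
  bad <- setdiff(unique(as.vector(rows)), RES_ALPHABET)
  if (length(bad) > 0)
    stop("symbols outside the 21-letter alphabet: ",
         paste(bad, collapse = ", "))
  rownames(rows) <- ids
  colnames(rows) <- NULL
  structure(list(ids = ids, rows = rows, provenance = provenance),
            class = "res_alignment")
}

#' @export
print.res_alignment <- function(x, ...) {
  cat(sprintf("res_alignment: %d sequences x %d columns\n",
              length(x$ids), ncol(x$rows)))
  invisible(x)
}

#' Read an aligned protein FASTA file
#'
#' All sequences must have identical length. Lowercase letters are
#' uppercased; ambiguity and non-standard codes (B, Z, X, U, O, J, `*`, `.`)
#' are mapped to the gap symbol with a warning, keeping the alphabet fixed at
#' the 20 canonical amino acids plus gap.
#'
#' @param path path to an aligned FASTA file.
#' @param format only `"fasta"` is supported.
#' @return a [new_alignment()] object.
#' @export
read_alignment <- function(path, format = "fasta") {
  format <- match.arg(format, "fasta")
  if (!file.exists(path)) stop("alignment file not found: ", path)
  recs <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) stop("could not parse FASTA in ",
                                            path, ": ", conditionMessage(e)))
  if (length(recs) == 0) stop("empty alignment file: ", path)
  chars <- strsplit(toupper(as.character(recs)), "")
  ids <- normalize_taxon(names(recs))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lens <- lengths(chars)
  if (length(unique(lens)) > 1) {
    ref <- lens[1]
    off <- ids[lens != ref][1]
    stop(sprintf(
      "sequence length mismatch: '%s' has length %d, expected %d",
      off, lens[ids == off][1], ref))
  }
  m <- do.call(rbind, chars)
  noncanon <- intersect(unique(as.vector(m)), NONCANONICAL_RESIDUES)
  if (length(noncanon) > 0) {
    warning("non-canonical residues mapped to gap: ",
            paste(noncanon, collapse = ", "))
    m[m %in% NONCANONICAL_RESIDUES] <- "-"
  }
  new_alignment(m, ids = ids,
                provenance = sprintf("read from %s", basename(path)))
}

#' Write an alignment as FASTA
#'
#' Sequences are written on a single line each, giving a canonical byte
#' representation (read-then-write round-trips exactly).
#'
#' @param alignment a `res_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "res_alignment"))
  seqs <- apply(alignment$rows, 1, paste, collapse = "")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0(">", alignment$ids, "\n", seqs), con, sep = "\n")
  invisible(path)
}

#' Read a rooted phylogenetic tree with branch lengths
#'
#' @param path newick file. The tree must be rooted, have a branch length on
#'   every edge, and all lengths must be non-negative; these are requirements
#'   of the Brownian-motion covariance downstream.
#' @return an [ape::phylo] tree with normalized tip labels.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick in ", path)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  validate_tree(tr)
}

#' Validate a phylo object for use in this package
#'
#' @param tr an [ape::phylo] tree.
#' @return the tree with normalized tip labels.
#' @export
validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylo object")
  if (ape::Ntip(tr) < 2) stop("tree has fewer than 2 tips")
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    stop("tree is missing branch lengths; all edges need a length")
  if (any(tr$edge.length < 0)) stop("negative branch length in tree")
  if (!ape::is.rooted(tr)) stop("tree must be rooted")
  tr$tip.label <- normalize_taxon(tr$tip.label)
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels in tree")
  tr
}

#' Write a tree as newick
#'
#' @param tree an [ape::phylo] tree.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a species trait table
#'
#' Expects a TSV (or CSV if the extension is `.csv`) with a `species` column
#' and at least one of `L_avg` (observed average lifespan, years) and `L_max`
#' (maximum lifespan, years). Rows with neither value are dropped with a
#' warning; non-positive lifespans are an error.
#'
#' @param path path to the table.
#' @return data.frame with columns `species`, `L_avg`, `L_max` (missing
#'   values as `NA`).
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop("trait file not found: ", path)
  df <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    read.csv(path, stringsAsFactors = FALSE)
  else
    read.delim(path, stringsAsFactors = FALSE)
  if (!"species" %in% names(df)) stop("trait table needs a 'species' column")
  if (!any(c("L_avg", "L_max") %in% names(df)))
    stop("trait table needs an 'L_avg' and/or 'L_max' column")
  if (!"L_avg" %in% names(df)) df$L_avg <- NA_real_
  if (!"L_max" %in% names(df)) df$L_max <- NA_real_
  df$species <- normalize_taxon(df$species)
  if (anyDuplicated(df$species)) stop("duplicate species in trait table")
  df$L_avg <- as.numeric(df$L_avg)
  df$L_max <- as.numeric(df$L_max)
  if (any(df$L_avg <= 0, na.rm = TRUE) || any(df$L_max <= 0, na.rm = TRUE))
    stop("lifespans must be positive")
  none <- is.na(df$L_avg) & is.na(df$L_max)
  if (any(none)) {
    warning("dropping ", sum(none), " species with no lifespan data: ",
            paste(df$species[none], collapse = ", "))
    df <- df[!none, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write a TSV result table
#'
#' UTF-8, tab-separated, `.` decimal separator, no quoting.
#'
#' @param df data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Restrict alignment, tree and trait table to their common taxa
#'
#' Taxon names are matched exactly after whitespace-to-underscore
#' normalization. All three inputs are restricted to the common taxon set in
#' the alignment's order; the tree is pruned accordingly. Dropped taxa are
#' reported via a message.
#'
#' @param alignment a `res_alignment`.
#' @param tree an [ape::phylo] tree.
#' @param traits trait data.frame (see [read_traits()]).
#' @return list with elements `alignment`, `tree`, `traits`, `dropped`
#'   (character vector of taxa not shared by all inputs).
#' @export
harmonize <- function(alignment, tree, traits) {
  stopifnot(inherits(alignment, "res_alignment"))
  tree <- validate_tree(tree)
  traits$species <- normalize_taxon(traits$species)
  common <- intersect(alignment$ids,
                      intersect(tree$tip.label, traits$species))
  if (length(common) < 3)
    stop("fewer than 3 taxa shared by alignment, tree and traits (",
         length(common), " found); PGLS needs at least 3")
  keep <- alignment$ids[alignment$ids %in% common]  # canonical order
  dropped <- setdiff(unique(c(alignment$ids, tree$tip.label, traits$species)),
                     common)
  if (length(dropped) > 0)
    message("harmonize: dropping ", length(dropped), " taxa: ",
            paste(dropped, collapse = ", "))
  aln <- new_alignment(alignment$rows[keep, , drop = FALSE], ids = keep,
                       provenance = alignment$provenance)
  tr <- ape::keep.tip(tree, keep)
  tra <- traits[match(keep, traits$species), , drop = FALSE]
  rownames(tra) <- NULL
  list(alignment = aln, tree = tr, traits = tra, dropped = dropped)
}
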