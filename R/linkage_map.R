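#' Linkage map container
#'
#' A `linkage_map` couples an ordered marker table with the genotype-class
#' codes observed in the mapping population.  Markers are grouped into
#' linkage groups and ordered by map position (centimorgan); each marker is
#' declared `testcross` (two genotype classes, expected 1:1 segregation) or
#' `intercross` (three classes, expected 1:2:1).  Genotype codes are opaque
#' strings: the mapping model only uses class membership, never allele phase.
#'
#' @param markers data.frame with columns `id`, `lg`, `pos_cM`, `seg_type`.
#' @param geno character matrix of genotype codes, one row per marker (in the
#'   same order as `markers`), one column per individual; `NA` marks a
#'   missing genotype.
#' @param n_dropped integer, number of markers removed by
#'   [dedup_markers()] (0 for a freshly read map).
#' @return An object of class `linkage_map`: a list with elements `markers`,
#'   `geno`, `individuals` and `n_dropped`.
#' @seealso [read_genotype_map()], [dedup_markers()], [classify_segregation()]
#' @export
linkage_map <- function(markers, geno, n_dropped = 0L) {
  stopifnot(is.data.frame(markers), is.matrix(geno))
  required <- c("id", "lg", "pos_cM", "seg_type")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols)) {
    stop("marker table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(markers) != nrow(geno)) {
    stop("marker table and genotype matrix disagree on marker count")
  }
  markers$id <- as.character(markers$id)
  markers$lg <- as.character(markers$lg)
  markers$pos_cM <- as.numeric(markers$pos_cM)
  markers$seg_type <- as.character(markers$seg_type)
  storage.mode(geno) <- "character"
  rownames(geno) <- markers$id
  if (is.null(colnames(geno))) {
    colnames(geno) <- paste0("ind", seq_len(ncol(geno)))
  }
  x <- structure(
    list(markers = markers, geno = geno,
         individuals = colnames(geno), n_dropped = as.integer(n_dropped)),
    class = "linkage_map")
  validate_linkage_map(x)
  x
}

validate_linkage_map <- function(x) {
  m <- x$markers
  dup <- m$id[duplicated(m$id)]
  if (length(dup)) {
    stop("duplicate marker id(s): ", paste(unique(dup), collapse = ", "))
  }
  bad_type <- setdiff(unique(m$seg_type), c("testcross", "intercross"))
  if (length(bad_type)) {
    stop("unknown seg_type token(s): ", paste(bad_type, collapse = ", "))
  }
  if (any(!is.finite(m$pos_cM)) || any(m$pos_cM < 0)) {
    stop("marker positions must be non-negative finite cM values")
  }
  for (g in unique(m$lg)) {
    pos <- m$pos_cM[m$lg == g]
    ids <- m$id[m$lg == g]
    drop <- which(diff(pos) < 0)
    if (length(drop)) {
      stop("position decreases within linkage group ", g,
           " at marker ", ids[drop[1] + 1])
    }
  }
  # declared class count is an upper bound for the observed one on read
  n_codes <- apply(x$geno, 1L, function(g) length(unique(g[!is.na(g)])))
  declared <- ifelse(m$seg_type == "testcross", 2L, 3L)
  over <- which(n_codes > declared)
  if (length(over)) {
    stop("marker ", m$id[over[1]], " declared ", m$seg_type[over[1]],
         " but shows ", n_codes[over[1]], " genotype classes")
  }
  invisible(x)
}

#' @export
print.linkage_map <- function(x, ...) {
  cat(sprintf(
    "linkage_map: %d markers on %d linkage group(s), %d individuals\n",
    nrow(x$markers), length(unique(x$markers$lg)), length(x$individuals)))
  tab <- table(x$markers$seg_type)
  cat("  seg types:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (x$n_dropped > 0) cat("  duplicate markers dropped:", x$n_dropped, "\n")
  invisible(x)
}

#' Number of markers / individuals in a linkage map
#' @param map a `linkage_map`.
#' @return integer count.
#' @export
n_markers <- function(map) nrow(map$markers)

#' @rdname n_markers
#' @export
n_individuals <- function(map) length(map$individuals)

#' Classify a marker's segregation type from its genotype codes
#'
#' Two distinct non-missing codes imply a testcross marker (one parent
#' heterozygous, 1:1 segregation), three imply an intercross marker (both
#' parents heterozygous, 1:2:1).
#'
#' @param genotypes character vector of genotype codes (`NA` = missing).
#' @return `"testcross"` or `"intercross"`.
#' @export
classify_segregation <- function(genotypes) {
  codes <- unique(genotypes[!is.na(genotypes)])
  k <- length(codes)
  if (k < 2L) stop("monomorphic marker: fewer than 2 genotype classes observed")
  if (k > 3L) stop("more than 3 genotype classes observed (", k, ")")
  if (k == 2L) "testcross" else "intercross"
}

#' Read a genotype/map file
#'
#' Expects tab-separated text with header
#' `marker lg pos_cM seg_type <ind1> <ind2> ...`; missing genotypes are `NA`.
#' Markers must be listed in non-decreasing map position within each linkage
#' group; linkage groups keep their order of first appearance.
#'
#' @param path path to the TSV file.
#' @return A [linkage_map()].
#' @export
read_genotype_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = "NA")
  if (ncol(df) < 5L) {
    stop("genotype/map file needs columns marker, lg, pos_cM, seg_type and at least one individual")
  }
  pos <- suppressWarnings(as.numeric(df[[3]]))
  bad <- which(is.na(pos) & !is.na(df[[3]]))
  if (length(bad)) {
    stop("non-numeric map position for marker ", df[[1]][bad[1]])
  }
  markers <- data.frame(id = df[[1]], lg = df[[2]], pos_cM = pos,
                        seg_type = df[[4]], stringsAsFactors = FALSE)
  geno <- as.matrix(df[, -(1:4), drop = FALSE])
  linkage_map(markers, geno)
}

#' Write a linkage map to a genotype/map TSV
#'
#' Inverse of [read_genotype_map()]: positions are written with enough digits
#' that a read/write/read cycle reproduces the object exactly.
#'
#' @param map a `linkage_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_map <- function(map, path) {
  out <- data.frame(marker = map$markers$id, lg = map$markers$lg,
                    pos_cM = sprintf("%.17g", map$markers$pos_cM),
                    seg_type = map$markers$seg_type,
                    stringsAsFactors = FALSE)
  geno <- map$geno
  geno[is.na(geno)] <- "NA"
  out <- cbind(out, as.data.frame(geno, stringsAsFactors = FALSE))
  names(out) <- c("marker", "lg", "pos_cM", "seg_type", map$individuals)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop markers with duplicated genotype vectors
#'
#' Markers whose genotype vectors are exactly identical across the whole
#' population (missing positions compared too) carry no independent mapping
#' information; only the first in map order is kept.  Such duplicates
#' typically arise when missing genotypes are imputed from neighbours on a
#' dense map.
#'
#' @param map a `linkage_map`.
#' @return A `linkage_map` whose `n_dropped` field reports how many markers
#'   were removed.
#' @export
dedup_markers <- function(map) {
  key <- apply(map$geno, 1L, function(g) {
    g[is.na(g)] <- "\x01NA\x01"
    paste(g, collapse = "\x1f")
  })
  dup <- duplicated(key)
  linkage_map(map$markers[!dup, , drop = FALSE],
              map$geno[!dup, , drop = FALSE],
              n_dropped = map$n_dropped + sum(dup))
}
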