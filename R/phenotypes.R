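#' Phenotype table container
#'
#' A `phenotype_table` is a data.frame whose first column, `individual`,
#' holds unique individual ids and whose remaining columns are numeric
#' traits (`NA` = not measured).  When paired with a [linkage_map()], the row
#' order must match the map's individual order; [read_phenotypes()] enforces
#' this when a map is supplied.
#'
#' @param df data.frame with an `individual` id column followed by numeric
#'   trait columns.
#' @return The data.frame with class `phenotype_table` prepended.
#' @export
phenotype_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (names(df)[1] != "individual") {
    names(df)[1] <- "individual"
  }
  df$individual <- as.character(df$individual)
  if (anyDuplicated(df$individual)) {
    stop("duplicate individual id(s): ",
         paste(unique(df$individual[duplicated(df$individual)]), collapse = ", "))
  }
  if (ncol(df) < 2L) stop("phenotype table has no trait columns")
  for (tr in names(df)[-1]) {
    if (!is.numeric(df[[tr]])) stop("trait column ", tr, " is not numeric")
  }
  rownames(df) <- NULL
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Trait names of a phenotype table
#' @param phen a `phenotype_table`.
#' @return character vector of trait column names.
#' @export
trait_names <- function(phen) setdiff(names(phen), "individual")

#' Read a phenotype file
#'
#' Delimited text (comma or tab, auto-detected from the header line unless
#' `sep` is given) with header `individual <trait1> <trait2> ...`.  Blank or
#' `NA` cells are missing values; any other non-numeric cell is a parse
#' error reported with its row and column.
#'
#' @param path path to the CSV/TSV file.
#' @param map optional [linkage_map()]; when supplied, individual ids are
#'   cross-checked (orphans on either side are an error) and rows are
#'   reordered to the map's individual order.
#' @param sep field separator; `NULL` (default) auto-detects `\t` vs `,`.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path, map = NULL, sep = NULL) {
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.delim(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(df) < 2L) stop("phenotype file needs an id column and at least one trait")
  out <- data.frame(individual = df[[1]], stringsAsFactors = FALSE)
  for (j in 2:ncol(df)) {
    raw <- df[[j]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw))
    if (length(bad)) {
      stop("non-numeric value \"", raw[bad[1]], "\" at (row ", bad[1],
           ", col \"", names(df)[j], "\")")
    }
    out[[names(df)[j]]] <- num
  }
  phen <- phenotype_table(out)
  if (!is.null(map)) phen <- align_phenotypes(map, phen)
  phen
}

#' Align a phenotype table with a linkage map
#'
#' Errors if either side has individuals the other lacks, then reorders the
#' phenotype rows to the map's individual order so that row i of the
#' phenotypes is the individual in genotype column i.
#'
#' @param map a `linkage_map`.
#' @param phen a `phenotype_table`.
#' @return The reordered `phenotype_table`.
#' @export
align_phenotypes <- function(map, phen) {
  only_phen <- setdiff(phen$individual, map$individuals)
  only_map <- setdiff(map$individuals, phen$individual)
  if (length(only_phen) || length(only_map)) {
    stop("individual id mismatch between map and phenotypes; ",
         "only in phenotypes: [", paste(only_phen, collapse = ", "),
         "]; only in map: [", paste(only_map, collapse = ", "), "]")
  }
  phen <- phen[match(map$individuals, phen$individual), , drop = FALSE]
  rownames(phen) <- NULL
  phen
}

#' Write a phenotype table
#'
#' Inverse of [read_phenotypes()]; numeric values are written with enough
#' digits for an exact read/write/read round trip.
#'
#' @param phen a `phenotype_table`.
#' @param path output path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phen, path, sep = ",") {
  out <- data.frame(individual = phen$individual, stringsAsFactors = FALSE)
  for (tr in trait_names(phen)) {
    v <- sprintf("%.17g", phen[[tr]])
    v[is.na(phen[[tr]])] <- "NA"
    out[[tr]] <- v
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' A trait pair
#'
#' @param trait1,trait2 distinct trait names.
#' @param phen optional `phenotype_table` to validate the names against.
#' @return character vector of length 2 with class `trait_pair`.
#' @export
trait_pair <- function(trait1, trait2, phen = NULL) {
  if (identical(trait1, trait2)) stop("trait pair must name two distinct traits")
  if (!is.null(phen)) {
    absent <- setdiff(c(trait1, trait2), trait_names(phen))
    if (length(absent)) {
      stop("trait(s) not in phenotype table: ", paste(absent, collapse = ", "))
    }
  }
  structure(c(trait1, trait2), class = "trait_pair")
}
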