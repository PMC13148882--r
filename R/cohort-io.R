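#' Call-token alphabet for presence/absence tables
#'
#' Maps cell tokens to phenotypes when reading call tables. Matching is
#' case-insensitive after trimming whitespace. The defaults cover the common
#' +/- band notation as well as 0/1 coding.
#'
#' @param present tokens read as the positive (band present) phenotype.
#' @param null tokens read as the null (deletion) phenotype.
#' @return list with elements \code{present} and \code{null}.
#' @export
callAlphabet <- function(present = c("1", "+", "present", "positive", "pos", "p"),
                         null = c("0", "-", "null", "neg", "absent")) {
  present <- tolower(present); null <- tolower(null)
  if (length(intersect(present, null)))
    stop("a token cannot map to both phenotypes")
  list(present = present, null = null)
}

#' Read a per-sample genotype call table
#'
#' Reads a delimited text file with a header row naming the sample-id column
#' and one column per locus, and returns a \linkS4class{GenotypeCohort}.
#' Sample order in the file is preserved.
#'
#' @param path file path.
#' @param sep field delimiter; tab is canonical, use "," for CSV.
#' @param idColumn name or index of the sample-id column (default: first).
#' @param alphabet token mapping from [callAlphabet()].
#' @return a \linkS4class{GenotypeCohort}.
#' @export
readCalls <- function(path, sep = "\t", idColumn = 1L,
                      alphabet = callAlphabet()) {
  df <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                   check.names = FALSE, quote = "", comment.char = "",
                   stringsAsFactors = FALSE)
  cols <- colnames(df)
  idName <- if (is.character(idColumn)) idColumn else cols[idColumn]
  if (is.na(idName) || !idName %in% cols)
    stop("sample-id column not found in header")
  lociNames <- setdiff(cols, idName)
  ids <- df[[idName]]
  if (anyDuplicated(ids))
    stop("duplicate sample_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- matrix(logical(0), nrow = length(lociNames), ncol = nrow(df),
              dimnames = list(lociNames, ids))
  for (l in lociNames) {
    v <- tolower(trimws(df[[l]]))
    isNull <- v %in% alphabet$null
    isPres <- v %in% alphabet$present
    bad <- which(!(isNull | isPres))
    if (length(bad))
      stop(sprintf("unrecognized call token '%s' at row %d, column '%s'",
                   df[[l]][bad[1]], bad[1], l))
    m[l, ] <- isNull
  }
  GenotypeCohort(m, metadata = list(source = path))
}

#' Write a genotype call table
#'
#' @param cohort a \linkS4class{GenotypeCohort}.
#' @param path output path.
#' @param sep field delimiter.
#' @param tokens two-element character vector naming the symbols written for
#'   the present and null phenotypes.
#' @return invisibly, the path.
#' @export
writeCalls <- function(cohort, path, sep = "\t",
                       tokens = c(present = "+", null = "-")) {
  m <- nullCalls(cohort)
  out <- data.frame(sample_id = colnames(m), check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (l in rownames(m))
    out[[l]] <- ifelse(m[l, ], tokens[["null"]], tokens[["present"]])
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a population frequency panel
#'
#' Reads a delimited text file with columns \code{population},
#' \code{region}, \code{n} and one null-genotype-frequency column per locus.
#' Blank cells are kept as missing values: a population with no frequency at
#' a locus is skipped by comparisons/distances at that locus rather than
#' treated as frequency 0.
#'
#' @param path file path.
#' @param sep field delimiter.
#' @param provenance provenance string stored on the panel (defaults to the
#'   path).
#' @return a \linkS4class{ReferencePanel} preserving file row order.
#' @export
readPanel <- function(path, sep = "\t", provenance = path) {
  df <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                   check.names = FALSE, quote = "", comment.char = "",
                   na.strings = c("", "NA"), stringsAsFactors = FALSE)
  if (!"population" %in% colnames(df))
    stop("panel needs a 'population' column")
  lociNames <- setdiff(colnames(df), c("population", "region", "n"))
  if ("n" %in% colnames(df)) {
    nNum <- suppressWarnings(as.numeric(df$n))
    badN <- !is.na(df$n) & (is.na(nNum) | nNum < 1 | nNum != floor(nNum))
    if (any(badN))
      stop("non-numeric or non-positive n for: ",
           paste(df$population[badN], collapse = ", "))
    df$n <- nNum
  }
  for (l in lociNames) {
    f <- suppressWarnings(as.numeric(df[[l]]))
    bad <- (!is.na(df[[l]]) & is.na(f)) | (!is.na(f) & (f < 0 | f > 1))
    if (any(bad))
      stop(sprintf("invalid %s frequency for: %s", l,
                   paste(df$population[bad], collapse = ", ")))
    df[[l]] <- f
  }
  ReferencePanel(df, loci = lociNames, provenance = provenance)
}

#' Write a population frequency panel
#'
#' Numeric fields are serialized at full precision so that
#' \code{readPanel(writePanel(p))} reproduces them exactly.
#'
#' @param panel a \linkS4class{ReferencePanel}.
#' @param path output path.
#' @param sep field delimiter.
#' @return invisibly, the path.
#' @export
writePanel <- function(panel, path, sep = "\t") {
  d <- as.data.frame(panel)
  d$n <- ifelse(is.na(d$n), "", format(d$n, trim = TRUE, scientific = FALSE))
  for (l in loci(panel))
    d[[l]] <- ifelse(is.na(d[[l]]),
                     "", format(d[[l]], digits = 17, trim = TRUE,
                                scientific = FALSE))
  write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' The packaged global GSTM1/GSTT1 reference panel
#'
#' Null genotype frequencies for the GSTM1 and GSTT1 deletions in 96 world
#' populations (Americas, Africa, Asia, Europe), compiled from published
#' surveys. Two records lack a stated sample size and one lacks a GSTM1
#' frequency; these feed distance calculations but are skipped by
#' count-based tests at the missing fields.
#'
#' @return a \linkS4class{ReferencePanel}.
#' @export
#' @examples
#' panel <- table3Panel()
#' nullFreq(panel, "GSTT1")[["Portuguese"]]
table3Panel <- function() {
  f <- system.file("extdata", "table3_panel.tsv", package = "nullmark",
                   mustWork = TRUE)
  readPanel(f, provenance = "packaged global survey of GSTM1/GSTT1 null genotype frequencies")
}
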