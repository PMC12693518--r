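## Enzyme table handling. The table is data, not code: the package ships the
## six assay enzymes in inst/extdata/enzymes.json and users may pass their own.

.bermass_cache <- new.env(parent = emptyenv())

#' Load a restriction/nicking enzyme table
#'
#' Reads an enzyme table from JSON. Each entry carries an IUPAC-degenerate
#' recognition string (top strand, 5' to 3'), cut offsets counted from the 5'
#' end of the recognition string on each strand, and a nicking annotation
#' (\code{none}, \code{top} or \code{bottom}).
#'
#' @param path JSON file; defaults to the table shipped with the package
#'   (NdeI, HaeII, PstI, BsoBI, Nt.BspQI, Nb.BbvCI).
#' @return data.frame with columns \code{name}, \code{recognition},
#'   \code{cut_offset_top}, \code{cut_offset_bottom}, \code{nicking}.
#' @examples
#' enz <- loadEnzymeTable()
#' enz[enz$name == "NdeI", ]
#' @export
loadEnzymeTable <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.bermass_cache$enzymes)) return(.bermass_cache$enzymes)
    path <- system.file("extdata", "enzymes.json", package = "bermass",
                        mustWork = TRUE)
    default <- TRUE
  } else default <- FALSE
  raw <- jsonlite::read_json(path)
  rows <- lapply(raw$enzymes, function(e) {
    data.frame(name = e$name, recognition = toupper(e$recognition),
               cut_offset_top = if (is.null(e$cut_offset_top)) NA_integer_
                                else as.integer(e$cut_offset_top),
               cut_offset_bottom = if (is.null(e$cut_offset_bottom)) NA_integer_
                                   else as.integer(e$cut_offset_bottom),
               nicking = e$nicking, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", tab$recognition)
  if (any(bad))
    stop("non-IUPAC recognition string for: ",
         paste(tab$name[bad], collapse = ", "))
  ok <- tab$nicking == "none"
  len <- nchar(tab$recognition)
  if (any(ok & (tab$cut_offset_top < 0 | tab$cut_offset_top > len |
                tab$cut_offset_bottom < 0 | tab$cut_offset_bottom > len)))
    stop("cut offsets of non-nicking enzymes must lie within the recognition string")
  if (default) .bermass_cache$enzymes <- tab
  tab
}

#' @keywords internal
.getEnzyme <- function(name, table = loadEnzymeTable()) {
  i <- match(name, table$name)
  if (is.na(i))
    stop("unknown enzyme name: ", name, " (configuration error)", call. = FALSE)
  as.list(table[i, ])
}

## IUPAC degeneracy map used for recognition-site scanning. U is equated with
## T (the enzymes read U-containing DNA); the abasic codes AP/rAP/F match
## nothing, so any site overlapping a lesioned residue is blocked.
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
                 H = "D", V = "B", N = "N")

#' @keywords internal
.revcompIUPAC <- function(pattern) {
  paste(rev(.COMPLEMENT[strsplit(pattern, "", fixed = TRUE)[[1]]]),
        collapse = "")
}
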