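#' Read a cluster or complex file
#'
#' Parses the de-facto plain-text format of complex-detection output
#' (MCL/ClusterONE style): one cluster per line, protein IDs separated
#' by any run of whitespace. Lines starting with the comment prefix and
#' blank lines are skipped; duplicate IDs within a line collapse to one
#' member; line order is preserved as cluster order.
#'
#' @param path file path (or connection) to read.
#' @param name method label for the resulting set; defaults to the
#'   file name without extension.
#' @param comment_prefix lines whose first non-whitespace character
#'   starts with this prefix are skipped. Default `"#"`.
#' @param min_cluster_size clusters with fewer members are dropped on
#'   read. Default 1 (no silent filtering).
#' @return a [cluster_set()].
#' @seealso [read_gold_standard()], [write_cluster_set()]
#' @export
read_cluster_set <- function(path, name = NULL, comment_prefix = "#",
                             min_cluster_size = 1L) {
  stopifnot(min_cluster_size >= 1L)
  if (is.null(name))
    name <- if (is.character(path)) sub("\\.[^.]*$", "", basename(path)) else "clusters"
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, comment_prefix)
  toks <- lapply(strsplit(lines[keep], "[[:space:]]+"), unique)
  toks <- toks[lengths(toks) >= min_cluster_size]
  if (length(toks) == 0L)
    stop("no clusters: file is empty after comment/blank/size filtering")
  cluster_set(toks, name = name)
}

#' Read a gold-standard complex file
#'
#' Same plain-text dialect as [read_cluster_set()]; the result is a
#' [gold_standard()].
#'
#' @inheritParams read_cluster_set
#' @return a [gold_standard()].
#' @export
read_gold_standard <- function(path, name = NULL, comment_prefix = "#",
                               min_cluster_size = 1L) {
  cs <- read_cluster_set(path, name = name, comment_prefix = comment_prefix,
                         min_cluster_size = min_cluster_size)
  gold_standard(cs$clusters, name = cs$name)
}

#' Write a cluster set to a plain-text file
#'
#' One cluster per line, members in lexicographic order, separated by a
#' single space; reading the file back yields the same clusters in the
#' same order.
#'
#' @param x a [cluster_set()] or [gold_standard()].
#' @param path output file path (or connection).
#' @return `path`, invisibly.
#' @export
write_cluster_set <- function(x, path) {
  stopifnot(inherits(x, "cluster_set"))
  writeLines(vapply(x$clusters, function(cl) paste(sort(cl), collapse = " "),
                    character(1)), con = path)
  invisible(path)
}

#' Read a weighted protein-protein interaction network
#'
#' Expects three whitespace-separated columns per line: the two
#' interacting protein IDs and a positive reliability weight. The
#' network is undirected: the duplicate of an already-seen edge (in
#' either orientation) is ignored. Self-interactions are dropped, and
#' the protein set consists of edge endpoints only, so the loaded
#' network never contains isolated proteins.
#'
#' @param path file path (or connection).
#' @return an object of class `ppin_network`: a list with `edges`
#'   (data.frame with columns `a`, `b`, `weight`) and `proteins`
#'   (character vector of endpoint IDs).
#' @export
read_weighted_edgelist <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  idx <- which(nzchar(lines) & !startsWith(lines, "#"))
  a <- b <- character(0); w <- numeric(0)
  seen <- character(0)
  for (li in idx) {
    f <- strsplit(lines[li], "[[:space:]]+")[[1]]
    if (length(f) != 3L)
      stop(sprintf("line %d: expected 3 columns (idA idB weight), got %d",
                   li, length(f)))
    wt <- suppressWarnings(as.numeric(f[3]))
    if (is.na(wt))
      stop(sprintf("line %d: non-numeric weight '%s'", li, f[3]))
    if (wt <= 0) {
      warning(sprintf("line %d: non-positive weight %g, line rejected", li, wt))
      next
    }
    if (f[1] == f[2]) next  # self-interaction
    key <- paste(sort(f[1:2]), collapse = "\r")
    if (key %in% seen) next  # first occurrence wins
    seen <- c(seen, key)
    a <- c(a, f[1]); b <- c(b, f[2]); w <- c(w, wt)
  }
  ppin_network(data.frame(a = a, b = b, weight = w, stringsAsFactors = FALSE))
}

#' Construct a PPIN object from an edge table
#'
#' @param edges data.frame with character columns `a`, `b` and numeric
#'   `weight` (> 0); self-edges and duplicate undirected edges are not
#'   permitted.
#' @return a `ppin_network` object.
#' @keywords internal
#' @export
ppin_network <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("a", "b", "weight") %in% names(edges)))
  if (nrow(edges)) {
    stopifnot(all(edges$a != edges$b), all(edges$weight > 0))
    key <- paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b))
    stopifnot(!anyDuplicated(key))
  }
  structure(
    list(edges = edges, proteins = sort(unique(c(edges$a, edges$b)))),
    class = "ppin_network"
  )
}

#' Write a PPIN as a three-column edge list
#'
#' @param x a `ppin_network`.
#' @param path output file path (or connection).
#' @return `path`, invisibly.
#' @export
write_weighted_edgelist <- function(x, path) {
  stopifnot(inherits(x, "ppin_network"))
  writeLines(sprintf("%s %s %.6g", x$edges$a, x$edges$b, x$edges$weight),
             con = path)
  invisible(path)
}

#' @export
print.ppin_network <- function(x, ...) {
  cat(sprintf("<PPI network: %d proteins, %d weighted edges>\n",
              length(x$proteins), nrow(x$edges)))
  invisible(x)
}
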