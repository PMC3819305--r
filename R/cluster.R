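#' @include expression.R
NULL

#' Correlation distance between two expression profiles
#'
#' `1 - Pearson r`, so identical profiles are at distance 0 and perfectly
#' anticorrelated ones at 2. Constant profiles have no defined correlation
#' and are an error.
#'
#' @param u,v numeric vectors of equal length >= 2.
#' @return the distance (in `[0, 2]`).
#' @export
profileDistance <- function(u, v) {
  stopifnot(length(u) == length(v), length(u) >= 2)
  if (sd(u) == 0 || sd(v) == 0)
    stop("correlation distance undefined for a constant profile")
  1 - cor(u, v)
}

# Correlation-distance matrix between the columns of m; names offending
# constant columns in the error.
.corDist <- function(m) {
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    stop("constant expression profile(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  as.dist(1 - cor(m))
}

#' Cluster libraries by their co-expressed miRNA profiles
#'
#' Restricts the matrix to the co-expressed (category-1) miRNAs, transforms
#' to `log2(RPM + 1)`, computes `1 - Pearson` distances between library
#' columns, and builds an average-linkage (UPGMA) dendrogram. Metric,
#' linkage and transform are the standard expression-profile configuration
#' and are exposed as arguments.
#'
#' @param x a [MirnaExperiment-class].
#' @param transform function applied to the RPM matrix (default
#'   `log2(rpm + 1)`).
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @param coexpressedOnly restrict to category-1 miRNAs (default `TRUE`).
#' @return an [stats::hclust] tree over the libraries.
#' @export
clusterLibraries <- function(x, transform = function(m) log2(m + 1),
                             linkage = "average", coexpressedOnly = TRUE) {
  stopifnot(is(x, "MirnaExperiment"))
  m <- rpm(x)
  if (coexpressedOnly) {
    cat1 <- categorize(x)$category == 1L
    if (!any(cat1)) stop("no co-expressed (category-1) miRNAs to cluster")
    m <- m[cat1, , drop = FALSE]
  }
  if (nrow(m) < 2) stop("need at least two miRNAs to cluster libraries")
  hclust(.corDist(transform(m)), method = linkage)
}

#' Cluster co-expressed miRNAs by their expression profiles
#'
#' Row-wise counterpart of [clusterLibraries()]: `1 - Pearson` distances
#' between miRNA profiles across libraries, average linkage.
#'
#' @inheritParams clusterLibraries
#' @return an [stats::hclust] tree over the miRNAs.
#' @export
clusterMirnas <- function(x, transform = function(m) log2(m + 1),
                          linkage = "average", coexpressedOnly = TRUE) {
  stopifnot(is(x, "MirnaExperiment"))
  m <- rpm(x)
  if (coexpressedOnly) {
    cat1 <- categorize(x)$category == 1L
    m <- m[cat1, , drop = FALSE]
  }
  if (nrow(m) < 3) stop("need at least three miRNAs to cluster")
  hclust(.corDist(t(transform(m))), method = linkage)
}

# Leaf sets of every internal node of an hclust tree.
.cladeMembers <- function(hc) {
  n <- nrow(hc$merge)
  members <- vector("list", n)
  for (i in seq_len(n)) {
    kids <- hc$merge[i, ]
    members[[i]] <- unlist(lapply(kids, function(k)
      if (k < 0) hc$labels[-k] else members[[k]]))
  }
  members
}

#' Does the dendrogram isolate the subcutaneous libraries?
#'
#' `TRUE` when the smallest clade containing all SAT libraries contains no
#' VAT library, i.e. the subcutaneous depots form their own subtree clearly
#' separated from the visceral ones.
#'
#' @param hc an [stats::hclust] tree whose leaves are the libraries.
#' @param depots named character vector (`VAT`/`SAT` per library label).
#' @return logical flag.
#' @examples
#' d <- matrix(1, 6, 6); diag(d) <- 0
#' d[5, 6] <- d[6, 5] <- 0.1
#' dimnames(d) <- rep(list(c("GOM", "MAD", "PAD", "RAD", "ULB", "ILB")), 2)
#' hc <- hclust(as.dist(d), "average")
#' depotSplit(hc, c(GOM = "VAT", MAD = "VAT", PAD = "VAT", RAD = "VAT",
#'                  ULB = "SAT", ILB = "SAT"))
#' @export
depotSplit <- function(hc, depots) {
  stopifnot(inherits(hc, "hclust"))
  if (!all(hc$labels %in% names(depots)))
    stop("missing depot label for: ",
         paste(setdiff(hc$labels, names(depots)), collapse = ", "))
  sats <- names(depots)[depots == "SAT"]
  sats <- intersect(sats, hc$labels)
  if (!length(sats)) stop("no SAT library among the leaves")
  if (length(sats) == 1) return(TRUE)
  members <- .cladeMembers(hc)
  containing <- Filter(function(m) all(sats %in% m), members)
  smallest <- containing[[which.min(lengths(containing))]]
  all(depots[smallest] == "SAT")
}

#' Write a dendrogram in Newick format
#'
#' Branch lengths derive from the UPGMA merge heights.
#'
#' @param hc an [stats::hclust] tree.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeDendrogram <- function(hc, path) {
  write.tree(as.phylo(hc), file = path)
  invisible(path)
}
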