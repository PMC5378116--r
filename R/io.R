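#' Read and write loci tables
#'
#' The on-disk format is tab-separated text with a one-line header and
#' columns \code{locus_id}, \code{state}, \code{s}, and optionally
#' \code{rel_rate}, \code{block}, \code{order_index} (see
#' [as_loci_table()]). Malformed rows are reported with their line number.
#'
#' @param path file path.
#' @return `read_loci` returns a validated loci table; `write_loci`
#'   (invisibly) the path.
#' @export
read_loci <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = NA)
  need <- c("locus_id", "state", "s")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  for (cl in c("state", "s", "rel_rate", "order_index")) {
    if (!cl %in% names(raw)) next
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(v) & !is.na(raw[[cl]]))
    if (length(bad))
      stop("non-numeric '", cl, "' at line ", bad[1] + 1L, " of ", path)
    raw[[cl]] <- v
  }
  tryCatch(as_loci_table(raw), error = function(e)
    stop("invalid loci table in ", path, ": ", conditionMessage(e)))
}

#' @rdname read_loci
#' @param table a loci table.
#' @export
write_loci <- function(table, path) {
  table <- as_loci_table(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Method-of-moments relative mutation rates from outgroup divergence
#'
#' Given the average number \eqn{\bar k_j} of pairwise differences between
#' ingroup and outgroup sequences at each locus, the relative mutation rate
#' of locus \eqn{j} is estimated as \eqn{\hat r_j = J \bar k_j / \sum_m \bar
#' k_m}, which is proportional to \eqn{\bar k_j} and has mean exactly 1.
#'
#' @param outgroup data frame with columns \code{locus_id} and \code{kbar}
#'   (average ingroup-outgroup pairwise differences; nonnegative).
#' @return Data frame \code{locus_id}, \code{rel_rate}.
#' @examples
#' estimate_relative_rates(data.frame(locus_id = c("a", "b"), kbar = c(1, 3)))
#' @export
estimate_relative_rates <- function(outgroup) {
  if (!all(c("locus_id", "kbar") %in% names(outgroup)))
    stop("outgroup table needs columns locus_id, kbar")
  k <- outgroup$kbar
  if (any(!is.finite(k)) || any(k < 0)) stop("kbar must be nonnegative")
  if (sum(k) <= 0) stop("all outgroup divergences are zero; rates undefined")
  data.frame(locus_id = as.character(outgroup$locus_id),
             rel_rate = length(k) * k / sum(k))
}

#' Partition loci into blocks of consecutive loci
#'
#' For linkage-aware analyses, loci are grouped into blocks of
#' \code{block_size} consecutive loci (by \code{order_index}) and,
#' optionally, every other block is discarded so that retained blocks are
#' separated by at least one block length of discarded sequence and can be
#' treated as independent clusters. Discarding starts with the first block
#' (\code{keep = "even"}), which also drops a trailing partial odd block;
#' \code{keep = "odd"} retains blocks 1, 3, ... including a partial tail.
#'
#' @param table a loci table with an \code{order_index} column.
#' @param block_size loci per block.
#' @param keep_alternate discard every other block (otherwise all blocks are
#'   kept and only labelled).
#' @param keep which alternating set to retain, \code{"even"} (default) or
#'   \code{"odd"}.
#' @return The filtered loci table with a \code{block} label column.
#' @export
block_reduce <- function(table, block_size, keep_alternate = TRUE,
                         keep = c("even", "odd")) {
  table <- as_loci_table(table)
  keep <- match.arg(keep)
  if (!"order_index" %in% names(table))
    stop("block_reduce needs an 'order_index' column (genome order)")
  if (block_size < 1) stop("block_size must be >= 1")
  ord <- order(table$order_index)
  table <- table[ord, , drop = FALSE]
  blk <- (seq_len(nrow(table)) - 1L) %/% as.integer(block_size) + 1L
  table$block <- sprintf("B%05d", blk)
  if (keep_alternate) {
    parity <- if (keep == "even") 0L else 1L
    table <- table[blk %% 2L == parity, , drop = FALSE]
  }
  rownames(table) <- NULL
  table
}
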