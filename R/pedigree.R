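#' Validate a pedigree table
#'
#' Checks and normalizes a three-column pedigree (individual, sire, dam).
#' IDs are treated as strings; `"0"`, `""`, `"NA"` and `NA` all encode an
#' unknown parent. Every named parent must itself be declared as an
#' individual, the pedigree must be acyclic, and IDs must be unique. Records
#' are returned in sorted topological order (parents before offspring, ties
#' broken by ID sort), which is also the row/column order of the
#' relationship matrix built from it.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam` (or the first
#'   three columns in that order).
#' @return a `pedigree_table`: data.frame `id`, `sire`, `dam` with `NA` for
#'   unknown parents, topologically sorted.
#' @examples
#' as_pedigree(data.frame(id = c("a", "b", "c"),
#'                        sire = c(0, 0, "a"), dam = c(0, 0, "b")))
#' @export
as_pedigree <- function(ped) {
  if (inherits(ped, "pedigree_table")) return(ped)
  ped <- as.data.frame(ped, stringsAsFactors = FALSE)
  if (ncol(ped) < 3L) stop("pedigree needs three columns: id, sire, dam")
  if (!all(c("id", "sire", "dam") %in% names(ped))) {
    names(ped)[1:3] <- c("id", "sire", "dam")
  }
  ped <- ped[, c("id", "sire", "dam")]
  norm <- function(x) {
    x <- trimws(as.character(x))
    x[x %in% c("0", "", "NA") | is.na(x)] <- NA_character_
    x
  }
  ped$id <- trimws(as.character(ped$id))
  ped$sire <- norm(ped$sire)
  ped$dam <- norm(ped$dam)
  if (anyNA(ped$id) || any(ped$id == "")) stop("individual IDs must be non-missing")
  if (anyDuplicated(ped$id)) {
    stop("duplicated individual IDs: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  }
  parents <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$id)
  if (length(parents)) {
    stop("parent IDs not declared as individuals: ",
         paste(parents, collapse = ", "))
  }
  # Kahn's algorithm, processing available individuals in sorted ID order
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  placed <- logical(n)
  order_out <- integer(0)
  repeat {
    avail <- which(!placed &
                     (is.na(ped$sire) | placed[idx[ped$sire]]) &
                     (is.na(ped$dam) | placed[idx[ped$dam]]))
    if (!length(avail)) break
    avail <- avail[order(ped$id[avail])]
    order_out <- c(order_out, avail)
    placed[avail] <- TRUE
  }
  if (length(order_out) < n) {
    bad <- ped$id[!placed][1L]
    stop("pedigree cycle detected involving individual '", bad, "'")
  }
  out <- ped[order_out, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree_table", "data.frame")
  out
}

#' Additive relationship matrix from a pedigree
#'
#' Builds the numerator relationship matrix A by the standard tabular
#' recursion: `A[i,i] = 1 + A[s,d] / 2` and `A[i,j] = (A[j,s] + A[j,d]) / 2`
#' for `j` preceding `i`, where unknown parents contribute 0. Founders have
#' diagonal exactly 1; A is symmetric positive semi-definite and equals
#' twice the kinship matrix.
#'
#' @param ped pedigree in any form accepted by [as_pedigree()].
#' @return symmetric numeric matrix with individual IDs as dimnames, in the
#'   sorted topological order of the pedigree.
#' @examples
#' ped <- data.frame(id = c("p", "q", "x"), sire = c(0, 0, "p"), dam = c(0, 0, "q"))
#' pedigree_relationship(ped)
#' @export
pedigree_relationship <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  ids <- ped$id
  pos <- seq_len(n)
  names(pos) <- ids
  si <- ifelse(is.na(ped$sire), 0L, pos[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, pos[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (s > 0L) A[j, s] else numeric(i - 1L)
      ad_ <- if (d > 0L) A[j, d] else numeric(i - 1L)
      v <- 0.5 * (as_ + ad_)
      A[j, i] <- v
      A[i, j] <- v
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

#' Read a pedigree file
#'
#' Reads a delimited pedigree with header `id,sire,dam` (comma or tab
#' separated) and validates it with [as_pedigree()].
#'
#' @param path file path.
#' @param sep field separator; guessed from the first line when `NULL`.
#' @return a `pedigree_table`.
#' @export
read_pedigree <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- guess_sep(path)
  ped <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE)
  as_pedigree(ped)
}

#' Write a pedigree file
#'
#' @param ped a `pedigree_table` (or coercible).
#' @param path output path; comma-separated with header `id,sire,dam`,
#'   unknown parents written as `0`.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  ped <- as_pedigree(ped)
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  atomic_write(path, function(f)
    utils::write.table(out, f, sep = ",", quote = FALSE, row.names = FALSE))
  invisible(path)
}
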