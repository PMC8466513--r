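#' Construct a validated pedigree
#'
#' A pedigree is a data frame with one row per animal and columns `id`,
#' `sire`, `dam` and `sex` (`"male"`/`"female"`, `NA` allowed). Unknown
#' parents are `NA`. Parents that are referenced but have no row of their
#' own are added as unknown-parent founders with the sex their role
#' implies. Sexes must be consistent with parental roles, ids unique, and
#' the parentage graph acyclic (checked by [topological_sort()]).
#'
#' @param df Data frame with columns `id`, `sire`, `dam` and optionally
#'   `sex`; empty strings are treated as unknown parents.
#' @return A data frame of class `"pedigree"`.
#' @export
pedigree <- function(df) {
  need <- c("id", "sire", "dam")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("pedigree lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  out <- data.frame(id = as.character(df$id),
                    sire = as.character(df$sire),
                    dam = as.character(df$dam),
                    sex = if ("sex" %in% names(df)) as.character(df$sex)
                          else NA_character_,
                    stringsAsFactors = FALSE)
  out$sire[!is.na(out$sire) & out$sire == ""] <- NA_character_
  out$dam[!is.na(out$dam) & out$dam == ""] <- NA_character_
  if (anyDuplicated(out$id))
    stop(sprintf("duplicate animal id(s): %s",
                 paste(unique(out$id[duplicated(out$id)]), collapse = ", ")),
         call. = FALSE)
  bad_sex <- !is.na(out$sex) & !out$sex %in% c("male", "female")
  if (any(bad_sex))
    stop("sex must be 'male', 'female' or NA", call. = FALSE)

  # implicit founders for referenced-but-absent parents
  ref_sires <- setdiff(stats::na.omit(out$sire), out$id)
  ref_dams <- setdiff(stats::na.omit(out$dam), out$id)
  both <- intersect(ref_sires, ref_dams)
  if (length(both))
    stop(sprintf("id(s) used as both sire and dam: %s",
                 paste(both, collapse = ", ")), call. = FALSE)
  if (length(ref_sires) || length(ref_dams)) {
    extra <- data.frame(id = c(ref_sires, ref_dams),
                        sire = NA_character_, dam = NA_character_,
                        sex = c(rep("male", length(ref_sires)),
                                rep("female", length(ref_dams))),
                        stringsAsFactors = FALSE)
    out <- rbind(extra, out)
  }
  # sex consistency with roles
  sires <- unique(stats::na.omit(out$sire))
  dams <- unique(stats::na.omit(out$dam))
  if (length(intersect(sires, dams)))
    stop("at least one animal appears as both sire and dam", call. = FALSE)
  sx <- out$sex[match(sires, out$id)]
  if (any(!is.na(sx) & sx != "male"))
    stop("a non-male animal is recorded as a sire", call. = FALSE)
  dx <- out$sex[match(dams, out$id)]
  if (any(!is.na(dx) & dx != "female"))
    stop("a non-female animal is recorded as a dam", call. = FALSE)
  if (any(out$id == out$sire | out$id == out$dam, na.rm = TRUE))
    stop("an animal is recorded as its own parent", call. = FALSE)
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Topologically sort a pedigree
#'
#' Reorders rows so that every parent precedes all of its offspring (Kahn's
#' algorithm). A cycle in the parentage graph is an error; one offending
#' cycle is reported.
#'
#' @param ped A [pedigree()].
#' @return The pedigree, parent-first ordered, with attribute `"sorted"`.
#' @export
topological_sort <- function(ped) {
  ped <- pedigree(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  parents <- cbind(idx[ped$sire], idx[ped$dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in parents[i, ]) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    left <- setdiff(seq_len(n), order)
    cycle <- .find_cycle(parents, left[1L])
    stop(sprintf("pedigree contains a parentage cycle: %s",
                 paste(ped$id[cycle], collapse = " -> ")), call. = FALSE)
  }
  out <- ped[order, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sorted") <- TRUE
  out
}

# walk parent links from a vertex on a cycle until a repeat is seen
.find_cycle <- function(parents, start) {
  seen <- integer(0)
  v <- start
  repeat {
    if (v %in% seen) {
      i <- which(seen == v)
      return(c(seen[i:length(seen)], v))
    }
    seen <- c(seen, v)
    nxt <- parents[v, ]
    nxt <- nxt[!is.na(nxt)]
    if (!length(nxt)) return(seen)  # defensive; cannot happen on a cycle
    v <- nxt[1L]
  }
}

.is_sorted_pedigree <- function(ped) {
  pos <- stats::setNames(seq_len(nrow(ped)), ped$id)
  sp <- pos[ped$sire]; dp <- pos[ped$dam]
  all(is.na(sp) | sp < seq_len(nrow(ped))) &&
    all(is.na(dp) | dp < seq_len(nrow(ped)))
}

#' Truncate a pedigree to a fixed number of ancestral generations
#'
#' Keeps each focal animal and its ancestors up to `generations` meioses
#' back (minimum over all paths from the focal set); more distant ancestors
#' are cut off by setting the parents of animals at the truncation depth to
#' unknown, turning them into founders.
#'
#' @param ped A [pedigree()].
#' @param focal_ids Ids whose ancestry should be retained (e.g. the
#'   phenotyped birds).
#' @param generations Number of meioses to retain (default 3).
#' @return A truncated [pedigree()].
#' @export
truncate_pedigree <- function(ped, focal_ids, generations = 3L) {
  ped <- pedigree(ped)
  generations <- as.integer(generations)
  if (is.na(generations) || generations < 0L)
    stop("generations must be a non-negative integer", call. = FALSE)
  focal_ids <- as.character(focal_ids)
  unknown <- setdiff(focal_ids, ped$id)
  if (length(unknown))
    stop(sprintf("focal id(s) not in pedigree: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  depth <- stats::setNames(rep(Inf, nrow(ped)), ped$id)
  depth[focal_ids] <- 0
  frontier <- focal_ids
  d <- 0
  while (length(frontier) && d < generations) {
    rows <- ped[match(frontier, ped$id), ]
    pars <- unique(stats::na.omit(c(rows$sire, rows$dam)))
    pars <- pars[depth[pars] > d + 1]
    depth[pars] <- d + 1
    frontier <- pars
    d <- d + 1
  }
  keep <- is.finite(depth)
  out <- ped[keep, , drop = FALSE]
  at_edge <- depth[out$id] >= generations
  out$sire[at_edge] <- NA_character_
  out$dam[at_edge] <- NA_character_
  rownames(out) <- NULL
  pedigree(out)
}

#' Additive relationship matrix by the tabular method
#'
#' Builds the numerator relationship matrix A over a parent-first ordered
#' pedigree: `A[i,i] = 1 + A[sire_i, dam_i] / 2` and, for j preceding i,
#' `A[i,j] = (A[j, sire_i] + A[j, dam_i]) / 2`, with missing-parent terms 0.
#' Unknown parents are treated as unrelated, non-inbred founders.
#'
#' @param ped A parent-first ordered [pedigree()] (see
#'   [topological_sort()]); unordered input is an error.
#' @return Symmetric numeric matrix with dimnames equal to the animal ids;
#'   founder diagonal 1, diagonals in `[1, 2]`, positive semidefinite.
#' @examples
#' ped <- pedigree(data.frame(id = c("s", "d", "x"), sire = c(NA, NA, "s"),
#'                            dam = c(NA, NA, "d")))
#' additive_relationship_matrix(topological_sort(ped))
#' @export
additive_relationship_matrix <- function(ped) {
  ped <- pedigree(ped)
  if (!.is_sorted_pedigree(ped))
    stop("pedigree is not parent-first ordered; call topological_sort() first",
         call. = FALSE)
  n <- nrow(ped)
  pos <- stats::setNames(seq_len(n), ped$id)
  si <- pos[ped$sire]; di <- pos[ped$dam]
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aj <- (if (!is.na(s)) A[j, s] else 0) + (if (!is.na(d)) A[j, d] else 0)
      A[j, i] <- A[i, j] <- aj / 2
    }
    A[i, i] <- 1 + (if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0)
  }
  A
}

#' Inbreeding coefficients from a pedigree
#'
#' @param ped A parent-first ordered [pedigree()].
#' @return Named numeric vector `F = diag(A) - 1`.
#' @export
inbreeding <- function(ped) {
  A <- additive_relationship_matrix(ped)
  diag(A) - 1
}
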