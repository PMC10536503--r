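#' Build and validate a pedigree
#'
#' @param records data frame with columns `id`, `sire`, `dam` and optionally
#'   `sex` ("M"/"F", 1/2 accepted) and `year` (birth year). Unknown parents
#'   are `NA`, `""` or `"0"`. Parents referenced but not listed are added as
#'   founders with sex inferred from their role.
#' @return A validated pedigree: a data frame of class
#'   `c("pedigree", "data.frame")` with normalized columns `id`, `sire`,
#'   `dam`, `sex`, `year` (plus any extra input columns). Errors on duplicate
#'   ids, ancestry cycles and sex conflicts (an id used both as sire and dam,
#'   or a recorded sex contradicting parental role).
#' @export
build_pedigree <- function(records) {
  ped <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(ped)))
    stop("pedigree records need columns id, sire, dam")
  ped$id <- as.character(ped$id)
  norm_parent <- function(x) {
    x <- as.character(x)
    x[x %in% c("", "0", "NA")] <- NA_character_
    x
  }
  ped$sire <- norm_parent(ped$sire)
  ped$dam <- norm_parent(ped$dam)
  if (anyDuplicated(ped$id))
    stop("duplicate pedigree ids: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  if (!"sex" %in% names(ped)) ped$sex <- NA_character_
  sex <- as.character(ped$sex)
  sex[sex %in% c("1", "m", "male")] <- "M"
  sex[sex %in% c("2", "f", "female")] <- "F"
  sex[!sex %in% c("M", "F")] <- NA_character_
  ped$sex <- sex
  if (!"year" %in% names(ped)) ped$year <- NA_integer_
  # auto-complete parents that are referenced but not listed
  missing_parents <- setdiff(c(ped$sire, ped$dam), c(ped$id, NA_character_))
  if (length(missing_parents)) {
    add <- data.frame(id = missing_parents, sire = NA_character_,
                      dam = NA_character_,
                      sex = ifelse(missing_parents %in% ped$sire, "M", "F"),
                      year = NA_integer_, stringsAsFactors = FALSE)
    for (extra in setdiff(names(ped), names(add))) add[[extra]] <- NA
    ped <- rbind(ped, add[, names(ped)])
  }
  # sex consistency with parental roles
  both <- intersect(ped$sire, ped$dam)
  both <- both[!is.na(both)]
  if (length(both))
    stop("sex conflict: used both as sire and dam: ",
         paste(both, collapse = ", "))
  as_sire <- ped$id %in% ped$sire
  as_dam <- ped$id %in% ped$dam
  bad <- (as_sire & !is.na(ped$sex) & ped$sex == "F") |
         (as_dam & !is.na(ped$sex) & ped$sex == "M")
  if (any(bad))
    stop("sex conflict: recorded sex contradicts parental role for: ",
         paste(ped$id[bad], collapse = ", "))
  ped$sex[as_sire & is.na(ped$sex)] <- "M"
  ped$sex[as_dam & is.na(ped$sex)] <- "F"
  .topo_order(ped)  # errors on cycles
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn topological order (parents before offspring); errors naming a cycle
.topo_order <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    ord <- c(ord, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n)
    stop("pedigree contains an ancestry cycle involving: ",
         paste(ped$id[setdiff(seq_len(n), ord)], collapse = ", "))
  ord
}

# parent row indices (possibly NA) for each row of ped
.parents_idx <- function(ped) {
  cbind(match(ped$sire, ped$id), match(ped$dam, ped$id))
}

# ancestor closure (row indices) of `rows`, truncated at `max_gen` meioses
.ancestor_closure <- function(ped, rows, max_gen = Inf) {
  pidx <- .parents_idx(ped)
  seen <- rows
  frontier <- rows
  g <- 0
  while (length(frontier) && g < max_gen) {
    frontier <- unique(stats::na.omit(as.vector(pidx[frontier, , drop = FALSE])))
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    g <- g + 1
  }
  sort(seen)
}

#' Additive (numerator) relationship matrix
#'
#' Computes Wright's numerator relationship matrix A over the ancestor
#' closure of the requested individuals by the recursive tabular method,
#' processing parents before offspring. Kinship coefficients are `A / 2`;
#' the diagonal equals `1 + F` where F is the inbreeding coefficient.
#' Ancestry is truncated at `max_generations` meioses above the requested
#' set; parents beyond the truncation are treated as unknown founders.
#'
#' @param ped a pedigree ([build_pedigree()]).
#' @param ids individuals to return (default: all). All are used together
#'   with their (truncated) ancestors during the recursion.
#' @param max_generations ancestry depth (default 15).
#' @return Symmetric matrix with `ids` as dimnames.
#' @export
additive_relationship <- function(ped, ids = ped$id, max_generations = 15L) {
  ped <- as.data.frame(ped)
  if (max_generations < 1L) stop("'max_generations' must be >= 1")
  rows <- match(ids, ped$id)
  if (anyNA(rows))
    stop("ids not in pedigree: ", paste(ids[is.na(rows)], collapse = ", "))
  keep <- .ancestor_closure(ped, rows, max_generations)
  sub <- ped[keep, , drop = FALSE]
  sub$sire[!sub$sire %in% sub$id] <- NA_character_
  sub$dam[!sub$dam %in% sub$id] <- NA_character_
  ord <- .topo_order(sub)
  n <- nrow(sub)
  pidx <- .parents_idx(sub)
  A <- matrix(0, n, n, dimnames = list(sub$id, sub$id))
  for (i in ord) {
    s <- pidx[i, 1]; d <- pidx[i, 2]
    a_sd <- if (!is.na(s) && !is.na(d)) A[s, d] else 0
    A[i, i] <- 1 + 0.5 * a_sd
    prev <- setdiff(seq_len(n), i)
    ai <- 0.5 * ((if (!is.na(s)) A[s, prev] else 0) +
                 (if (!is.na(d)) A[d, prev] else 0))
    A[i, prev] <- ai
    A[prev, i] <- ai
  }
  A[match(ids, sub$id), match(ids, sub$id), drop = FALSE]
}

#' Categorize a's relationship to b
#'
#' Returns every pedigree category that holds for the ordered pair:
#' `parent`, `offspring`, `full-sib`, `half-sib`, `grandparent`,
#' `great-grandparent`, `grandchild`, `avuncular` (a is a full or half
#' sibling of one of b's parents). A pair can satisfy several categories in
#' an inbred pedigree.
#'
#' @param ped a pedigree.
#' @param a,b distinct individual ids.
#' @return Character vector of categories (possibly empty).
#' @export
relation_category <- function(ped, a, b) {
  ped <- as.data.frame(ped)
  ia <- match(a, ped$id); ib <- match(b, ped$id)
  if (is.na(ia) || is.na(ib))
    stop("unknown id: ", paste(c(a, b)[is.na(c(ia, ib))], collapse = ", "))
  if (a == b) stop("a and b must differ")
  pidx <- .parents_idx(ped)
  parents <- function(i) stats::na.omit(pidx[i, ])
  gparents <- function(i) unique(unlist(lapply(parents(i), parents)))
  ggparents <- function(i) unique(unlist(lapply(gparents(i), parents)))
  sibs <- function(i, j) {
    # shared-parent categories, requiring at least one known shared parent
    pi <- pidx[i, ]; pj <- pidx[j, ]
    shared <- sum(!is.na(pi) & !is.na(pj) & pi == pj)
    known <- sum(!is.na(pi) & !is.na(pj))
    if (shared == 2L) "full-sib" else if (shared == 1L) "half-sib" else NULL
  }
  out <- character(0)
  if (ia %in% parents(ib)) out <- c(out, "parent")
  if (ib %in% parents(ia)) out <- c(out, "offspring")
  out <- c(out, sibs(ia, ib))
  if (ia %in% gparents(ib)) out <- c(out, "grandparent")
  if (ia %in% ggparents(ib)) out <- c(out, "great-grandparent")
  if (ib %in% gparents(ia)) out <- c(out, "grandchild")
  for (p in parents(ib)) {
    if (!is.null(sibs(ia, p))) { out <- c(out, "avuncular"); break }
  }
  unique(out)
}

#' Classify a genotyped cohort into cases, carriers, controls and exclusions
#'
#' Applies the pedigree-informed status rules for a recessive-model GWAS, in
#' fixed order:
#' \enumerate{
#'   \item cases with an ambiguous diagnosis are excluded
#'     (`excluded_diagnosis`);
#'   \item optionally, T-cell cases are excluded (`excluded_diagnosis`);
#'   \item remaining confirmed cases are `case` (y = 2);
#'   \item genotyped non-cases that are parents of at least one case,
#'     offspring of at least one case, or grandparents/great-grandparents of
#'     at least two cases are `carrier` (y = 1);
#'   \item remaining dogs that are full or half siblings, grandchildren or
#'     aunts/uncles of a case, grandparents/great-grandparents of exactly one
#'     case, or that have PIHAT above `pihat_threshold` with any genotyped
#'     case, are `excluded_relative` (their carrier status is uncertain);
#'   \item everything else is `control` (y = 0).
#' }
#' Ungenotyped cases participate in the relative rules (carrier status is a
#' pedigree property), but only genotyped dogs appear in the output. The
#' carrier rule takes precedence over exclusion, so a dog that qualifies as
#' both is a carrier.
#'
#' @param ped a pedigree.
#' @param case_ids ids of all diagnosed cases (genotyped or not).
#' @param genotyped_ids ids of the genotyped cohort.
#' @param diagnoses optional data frame (`id`, `ambiguous` logical,
#'   `immunophenotype` in "B"/"T"/"untyped"/NA) refining the case list.
#' @param pihat optional data frame (`id1`, `id2`, `pihat`) of pairwise IBD
#'   estimates used by the relatedness exclusion.
#' @param pihat_threshold exclusion threshold, default 0.25 (first/second
#'   degree).
#' @param drop_tcell exclude T-cell cases (default TRUE).
#' @return Data frame of class `"status_assignment"`: `id`, `status`, `y`
#'   (2/1/0, NA for exclusions), `reason`.
#' @export
classify_cohort <- function(ped, case_ids, genotyped_ids, diagnoses = NULL,
                            pihat = NULL, pihat_threshold = 0.25,
                            drop_tcell = TRUE) {
  ped <- as.data.frame(ped)
  genotyped_ids <- sort(as.character(genotyped_ids))
  case_ids <- as.character(case_ids)
  status <- stats::setNames(rep(NA_character_, length(genotyped_ids)),
                            genotyped_ids)
  reason <- stats::setNames(rep(NA_character_, length(genotyped_ids)),
                            genotyped_ids)
  excluded_cases <- character(0)
  if (!is.null(diagnoses)) {
    amb <- diagnoses$id[isTRUE_vec(diagnoses$ambiguous)]
    excluded_cases <- intersect(case_ids, amb)
    tc <- character(0)
    if (drop_tcell && "immunophenotype" %in% names(diagnoses)) {
      tc <- diagnoses$id[!is.na(diagnoses$immunophenotype) &
                           diagnoses$immunophenotype == "T"]
      tc <- setdiff(intersect(case_ids, tc), excluded_cases)
    }
    for (id in intersect(excluded_cases, genotyped_ids)) {
      status[id] <- "excluded_diagnosis"; reason[id] <- "ambiguous_diagnosis"
    }
    for (id in intersect(tc, genotyped_ids)) {
      status[id] <- "excluded_diagnosis"; reason[id] <- "t_cell"
    }
    # T-cell cases are still lymphoma cases for the relative rules;
    # ambiguous diagnoses are not
    case_ids <- setdiff(case_ids, excluded_cases)
    gwas_cases <- setdiff(case_ids, tc)
  } else {
    gwas_cases <- case_ids
  }
  ungenotyped <- setdiff(gwas_cases, genotyped_ids)
  if (length(ungenotyped))
    message(length(ungenotyped),
            " case(s) not genotyped; used for relative rules only: ",
            paste(utils::head(ungenotyped, 5L), collapse = ", "))
  for (id in intersect(gwas_cases, genotyped_ids)) {
    if (is.na(status[id])) status[id] <- "case"
  }
  case_in_ped <- intersect(case_ids, ped$id)
  rest <- genotyped_ids[is.na(status)]
  if (length(case_in_ped) && length(rest)) {
    pidx <- .parents_idx(ped)
    rowid <- stats::setNames(seq_len(nrow(ped)), ped$id)
    parents_of <- function(rows) unique(stats::na.omit(as.vector(
      pidx[rows, , drop = FALSE])))
    crow <- rowid[case_in_ped]
    case_parents <- lapply(crow, function(r) parents_of(r))
    case_gparents <- lapply(case_parents, parents_of)
    case_ggparents <- lapply(case_gparents, parents_of)
    # counts, per pedigree row, of cases this row is parent / gp-or-ggp of
    count_in <- function(sets) {
      t <- table(unlist(sets))
      out <- integer(nrow(ped))
      out[as.integer(names(t))] <- as.integer(t)
      out
    }
    n_parent_of <- count_in(case_parents)
    n_gp_of <- count_in(mapply(function(g, gg) unique(c(g, gg)),
                               case_gparents, case_ggparents,
                               SIMPLIFY = FALSE))
    for (id in rest) {
      r <- rowid[id]
      if (is.na(r)) next
      my_parents <- parents_of(r)
      my_gparents <- parents_of(my_parents)
      is_child_of_case <- any(crow %in% my_parents)
      sib_of_case <- length(my_parents) > 0L &&
        any(vapply(case_parents, function(ps)
          length(intersect(ps, my_parents)) > 0L, logical(1)))
      grandchild_of_case <- any(crow %in% my_gparents)
      # avuncular: this dog shares a parent with one of the case's parents
      avunc <- length(my_parents) > 0L &&
        any(vapply(case_parents, function(ps) {
          if (!length(ps)) return(FALSE)
          gp_of_case <- lapply(ps, function(p) parents_of(p))
          any(vapply(gp_of_case, function(cpp)
            length(intersect(cpp, my_parents)) > 0L, logical(1)))
        }, logical(1)))
      if (n_parent_of[r] >= 1L) {
        status[id] <- "carrier"; reason[id] <- "parent_of_case"
      } else if (is_child_of_case) {
        status[id] <- "carrier"; reason[id] <- "offspring_of_case"
      } else if (n_gp_of[r] >= 2L) {
        status[id] <- "carrier"; reason[id] <- "grandparent_of_two_cases"
      } else if (sib_of_case) {
        status[id] <- "excluded_relative"; reason[id] <- "sibling_of_case"
      } else if (grandchild_of_case) {
        status[id] <- "excluded_relative"; reason[id] <- "grandchild_of_case"
      } else if (avunc) {
        status[id] <- "excluded_relative"; reason[id] <- "avuncular_of_case"
      } else if (n_gp_of[r] == 1L) {
        status[id] <- "excluded_relative"; reason[id] <- "grandparent_of_one_case"
      }
    }
  }
  if (!is.null(pihat) && nrow(pihat)) {
    gcases <- intersect(gwas_cases, genotyped_ids)
    hit <- (pihat$id1 %in% gcases | pihat$id2 %in% gcases) &
      pihat$pihat > pihat_threshold
    flagged <- unique(c(pihat$id1[hit], pihat$id2[hit]))
    flagged <- setdiff(intersect(flagged, genotyped_ids), gcases)
    for (id in flagged) {
      if (is.na(status[id])) {
        status[id] <- "excluded_relative"; reason[id] <- "pihat"
      }
    }
  }
  status[is.na(status)] <- "control"
  y <- ifelse(status == "case", 2L, ifelse(status == "carrier", 1L,
              ifelse(status == "control", 0L, NA_integer_)))
  out <- data.frame(id = genotyped_ids, status = unname(status),
                    y = unname(y), reason = unname(reason),
                    stringsAsFactors = FALSE)
  class(out) <- c("status_assignment", "data.frame")
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Common ancestors of a set of cases
#'
#' Intersects the ancestor closures of the listed cases and ranks the shared
#' ancestors by birth year (most recent first, so the nearest common
#' ancestors such as shared parents head the list; unknown years last), then
#' by the summed minimum path length to the cases, then by id. Cases without any
#' pedigree link contribute an empty closure, so the result is empty if any
#' case is disconnected from the rest.
#'
#' @param ped a pedigree.
#' @param case_ids ids (at least 2) present in the pedigree.
#' @param max_generations ancestry truncation (default unlimited).
#' @return Data frame `id`, `year`, `total_path` (summed minimum meiosis
#'   counts), `n_cases` (cases descending from the ancestor), ranked; empty
#'   if there is no common ancestor.
#' @export
common_ancestors <- function(ped, case_ids, max_generations = Inf) {
  ped <- as.data.frame(ped)
  rows <- match(case_ids, ped$id)
  if (anyNA(rows))
    stop("ids not in pedigree: ",
         paste(case_ids[is.na(rows)], collapse = ", "))
  if (length(rows) < 2L) stop("need at least two cases")
  pidx <- .parents_idx(ped)
  # per-case map: ancestor row -> min path length (meioses)
  depth_map <- function(r) {
    d <- stats::setNames(0L, as.character(r))
    frontier <- r
    g <- 0L
    while (length(frontier) && g < max_generations) {
      nxt <- integer(0)
      for (i in frontier) {
        for (p in stats::na.omit(pidx[i, ])) {
          key <- as.character(p)
          if (!key %in% names(d)) {
            d[key] <- g + 1L
            nxt <- c(nxt, p)
          }
        }
      }
      frontier <- nxt
      g <- g + 1L
    }
    d
  }
  maps <- lapply(rows, depth_map)
  anc_sets <- lapply(seq_along(maps), function(k)
    setdiff(as.integer(names(maps[[k]])), rows[k]))
  common <- Reduce(intersect, anc_sets)
  if (!length(common))
    return(data.frame(id = character(0), year = integer(0),
                      total_path = integer(0), n_cases = integer(0)))
  total_path <- vapply(common, function(a)
    sum(vapply(maps, function(m) m[[as.character(a)]], integer(1))), integer(1))
  out <- data.frame(id = ped$id[common], year = ped$year[common],
                    total_path = total_path,
                    n_cases = length(rows), stringsAsFactors = FALSE)
  out <- out[order(is.na(out$year), -xtfrm(out$year), out$total_path, out$id),
             , drop = FALSE]
  rownames(out) <- NULL
  out
}
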