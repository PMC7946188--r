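#' Define a pedigree from trio rows
#'
#' @param trios data.frame with columns `child`, `mother`, `father`; use `NA`
#'   or `"0"` for an unknown parent. Parents that never appear as children are
#'   founders; founders may be unsampled placeholders.
#' @return A `pedigree` object: member ids, per-member mother/father indices,
#'   and a topological order (founders first).
#' @export
pedigree <- function(trios) {
  stopifnot(is.data.frame(trios), all(c("child", "mother", "father") %in% names(trios)))
  norm <- function(v) { v <- as.character(v); v[v %in% c("0", "")] <- NA; v }
  child <- as.character(trios$child)
  mother <- norm(trios$mother); father <- norm(trios$father)
  if (anyDuplicated(child)) stop("a child appears in more than one trio row")
  members <- unique(c(child, mother[!is.na(mother)], father[!is.na(father)]))
  mo <- fa <- rep(NA_integer_, length(members))
  ci <- match(child, members)
  mo[ci] <- match(mother, members)
  fa[ci] <- match(father, members)
  # topological order: repeatedly emit members whose parents are all emitted
  parent_placed <- function(p, placed) is.na(p) | placed[replace(p, is.na(p), 1L)]
  placed <- is.na(mo) & is.na(fa)
  order_idx <- which(placed)
  while (length(order_idx) < length(members)) {
    ready <- which(!placed & parent_placed(mo, placed) & parent_placed(fa, placed))
    if (!length(ready)) stop("pedigree contains a cycle")
    placed[ready] <- TRUE
    order_idx <- c(order_idx, ready)
  }
  structure(list(members = members, mother = mo, father = fa,
                 topo = order_idx),
            class = "pedigree")
}

#' Expected kinship between two pedigree members
#'
#' Standard recursive kinship over the pedigree DAG, with founders assumed
#' unrelated and non-inbred (inbreeding is ignored throughout, so
#' phi(a, a) = 1/2).
#'
#' @param ped A [pedigree()].
#' @param id_a,id_b Member ids.
#' @return List with `phi` (kinship coefficient) and `r` (= 2 * phi, the
#'   expected relatedness coefficient).
#' @export
expected_kinship <- function(ped, id_a, id_b) {
  stopifnot(inherits(ped, "pedigree"))
  ia <- match(id_a, ped$members); ib <- match(id_b, ped$members)
  if (is.na(ia)) stop("id not in pedigree: ", id_a)
  if (is.na(ib)) stop("id not in pedigree: ", id_b)
  depth <- integer(length(ped$members))
  for (i in ped$topo) {
    pd <- c(if (!is.na(ped$mother[i])) depth[ped$mother[i]],
            if (!is.na(ped$father[i])) depth[ped$father[i]])
    depth[i] <- if (length(pd)) max(pd) + 1L else 0L
  }
  memo <- new.env(parent = emptyenv())
  phi <- function(i, j) {
    if (i > j) { k <- i; i <- j; j <- k }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      0.5
    } else {
      # recurse on the member deeper in the pedigree
      if (depth[j] < depth[i]) { k <- i; i <- j; j <- k }
      if (is.na(ped$mother[j]) && is.na(ped$father[j])) {
        0
      } else {
        pm <- if (is.na(ped$mother[j])) 0 else phi(i, ped$mother[j])
        pf <- if (is.na(ped$father[j])) 0 else phi(i, ped$father[j])
        0.5 * (pm + pf)
      }
    }
    memo[[key]] <- val
    val
  }
  p <- phi(ia, ib)
  list(phi = p, r = 2 * p)
}

degree_rank <- function(degree, windows = default_degree_windows()) {
  match(degree, c(names(windows), "unrelated"))
}

#' Check a proposed pedigree against genetic evidence
#'
#' Four rules are evaluated for every applicable pair or trio of sampled
#' members (unsampled founders are exempt):
#' * R1: a child carries its mother's mtDNA lineage;
#' * R2: a son carries his father's Y lineage;
#' * R3: the observed degree class of every in-pedigree pair matches the
#'   class expected from the pedigree (one class of slack is allowed, and
#'   "unresolved" calls are not violations, reflecting pseudo-haploid noise);
#' * R4: parental roles match genetic sex calls (a sampled mother must not be
#'   called male, a sampled father not female).
#'
#' @param ped A [pedigree()].
#' @param profiles data.frame with `individual_id`, `mt_lineage`,
#'   `y_lineage` (NA for females), `sex_call`. Members present here count as
#'   sampled.
#' @param kinship A `kinship_result` from [kinship_table()], or its `table`.
#' @param windows Degree windows used for the expected class.
#' @return data.frame of findings: `rule_id`, `ids`, `status`
#'   ("ok"/"violation"), `detail`.
#' @export
check_consistency <- function(ped, profiles, kinship,
                              windows = default_degree_windows()) {
  stopifnot(inherits(ped, "pedigree"), is.data.frame(profiles))
  ktab <- if (inherits(kinship, "kinship_result")) kinship$table else kinship
  sampled <- ped$members[ped$members %in% profiles$individual_id]
  prof <- profiles[match(sampled, profiles$individual_id), ]
  pget <- function(id, col) prof[[col]][match(id, prof$individual_id)]
  findings <- list()
  add <- function(rule, ids, status, detail)
    findings[[length(findings) + 1L]] <<- data.frame(
      rule_id = rule, ids = paste(ids, collapse = "+"),
      status = status, detail = detail, stringsAsFactors = FALSE)

  for (i in seq_along(ped$members)) {
    id <- ped$members[i]
    if (!(id %in% sampled)) next
    mo <- ped$mother[i]; fa <- ped$father[i]
    if (!is.na(mo) && ped$members[mo] %in% sampled) {
      mid <- ped$members[mo]
      same <- identical(pget(id, "mt_lineage"), pget(mid, "mt_lineage"))
      add("R1", c(id, mid), if (same) "ok" else "violation",
          sprintf("child mt %s vs mother mt %s",
                  pget(id, "mt_lineage"), pget(mid, "mt_lineage")))
      if (identical(pget(mid, "sex_call"), "M"))
        add("R4", c(id, mid), "violation", "proposed mother has male sex call")
      else add("R4", c(id, mid), "ok", "mother sex call compatible")
    }
    if (!is.na(fa) && ped$members[fa] %in% sampled) {
      fid <- ped$members[fa]
      if (identical(pget(id, "sex_call"), "M")) {
        same <- identical(pget(id, "y_lineage"), pget(fid, "y_lineage"))
        add("R2", c(id, fid), if (same) "ok" else "violation",
            sprintf("son Y %s vs father Y %s",
                    pget(id, "y_lineage"), pget(fid, "y_lineage")))
      }
      if (identical(pget(fid, "sex_call"), "F"))
        add("R4", c(id, fid), "violation", "proposed father has female sex call")
      else add("R4", c(id, fid), "ok", "father sex call compatible")
    }
  }

  if (length(sampled) >= 2) {
    combs <- utils::combn(sampled, 2)
    for (k in seq_len(ncol(combs))) {
      a <- combs[1, k]; b <- combs[2, k]
      exp_r <- expected_kinship(ped, a, b)$r
      exp_cls <- classify_degree(exp_r, 0, windows)
      row <- ktab[(ktab$id_a == a & ktab$id_b == b) |
                    (ktab$id_a == b & ktab$id_b == a), ]
      if (!nrow(row) || is.na(row$degree[1])) next
      obs <- row$degree[1]
      ok <- obs == "unresolved" ||
        abs(degree_rank(obs, windows) - degree_rank(exp_cls, windows)) <= 1
      add("R3", c(a, b), if (ok) "ok" else "violation",
          sprintf("expected %s (r = %.3f), observed %s (r = %.3f)",
                  exp_cls, exp_r, obs, row$r[1]))
    }
  }
  if (!length(findings))
    return(data.frame(rule_id = character(), ids = character(),
                      status = character(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

#' Uniparental lineage diversity of a cohort
#'
#' @param profiles data.frame with `individual_id`, `mt_lineage`,
#'   `y_lineage`, `sex_call`. Y lineages are counted over males only.
#' @return List: `n_mt_lineages`, `n_y_lineages`, `mt_counts`, `y_counts`.
#' @export
lineage_diversity <- function(profiles) {
  stopifnot(is.data.frame(profiles), nrow(profiles) > 0)
  mt <- profiles$mt_lineage[!is.na(profiles$mt_lineage)]
  yl <- profiles$y_lineage[profiles$sex_call == "M" & !is.na(profiles$y_lineage)]
  list(n_mt_lineages = length(unique(mt)),
       n_y_lineages = length(unique(yl)),
       mt_counts = table(mt), y_counts = table(yl))
}

#' Fraction of a cohort without close kin
#'
#' The fraction of cohort individuals with no relative at third degree or
#' closer in the kinship table.
#'
#' @param kinship A `kinship_result` from [kinship_table()].
#' @param cohort Character vector of individual ids (defaults to all ids in
#'   the kinship table).
#' @return Fraction in `[0, 1]`.
#' @export
unrelated_fraction <- function(kinship, cohort = NULL) {
  ktab <- if (inherits(kinship, "kinship_result")) kinship$table else kinship
  if (is.null(cohort)) cohort <- unique(c(ktab$id_a, ktab$id_b))
  close <- !is.na(ktab$degree) &
    ktab$degree %in% c("identical", "first", "second", "third")
  close_ids <- unique(c(ktab$id_a[close], ktab$id_b[close]))
  1 - sum(cohort %in% close_ids) / length(cohort)
}
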