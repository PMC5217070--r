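#' Assign phantom parents to genetic groups
#'
#' Every unknown-parent slot in the pedigree receives a phantom parent drawn
#' from one of `r` genetic groups. Assignments may be hard (one group per
#' slot) or fuzzy (a membership probability vector over groups, see
#' [fuzzy_memberships()]). The result is a grouped pedigree: the same tibble
#' with group metadata attached.
#'
#' Rules:
#' \describe{
#'   \item{`"single"`}{one group for every phantom parent (the classical
#'     single base population).}
#'   \item{`"flag"`}{two groups from the logical `immigrant` column: phantom
#'     parents of immigrants go to the second group, all others (founders and
#'     other natives with unknown parents) to the first. This is the natural
#'     grouping when immigrants are genetically distinct.}
#'   \item{`"cohort"`}{one group per cohort value among records with unknown
#'     parents.}
#'   \item{`"table"`}{explicit lookup: `table` has column `id` plus either
#'     `group` (both slots) or `dam_group`/`sire_group`.}
#' }
#'
#' @param ped ordered pedigree tibble.
#' @param rule grouping rule; see Details.
#' @param labels group labels; sensible defaults per rule.
#' @param reference label of the reference group whose mean effect is fixed
#'   at zero. Defaults to the first (founder) group.
#' @param table lookup table for `rule = "table"`.
#' @return a `gg_grouped_ped`: the pedigree tibble with attributes holding the
#'   group labels, the reference group and per-slot membership matrices.
#' @export
assign_groups <- function(ped, rule = c("single", "flag", "cohort", "table"),
                          labels = NULL, reference = NULL, table = NULL) {
  rule <- match.arg(rule)
  assert_ordered(ped)
  n <- nrow(ped)
  ud <- is.na(ped$dam); us <- is.na(ped$sire)

  if (rule == "single") {
    labels <- labels %||% "g1"
    stopifnot(length(labels) == 1)
    grp_dam <- ifelse(ud, labels, NA_character_)
    grp_sire <- ifelse(us, labels, NA_character_)
  } else if (rule == "flag") {
    if (!"immigrant" %in% names(ped))
      abort("rule = 'flag' needs an 'immigrant' logical column")
    labels <- labels %||% c("founder", "immigrant")
    stopifnot(length(labels) == 2)
    imm <- isTRUE_vec(ped$immigrant)
    grp_dam <- ifelse(ud, ifelse(imm, labels[2], labels[1]), NA_character_)
    grp_sire <- ifelse(us, ifelse(imm, labels[2], labels[1]), NA_character_)
  } else if (rule == "cohort") {
    if (!"cohort" %in% names(ped))
      abort("rule = 'cohort' needs a 'cohort' column")
    coh <- ped$cohort
    if (any(is.na(coh[ud | us])))
      abort(sprintf("cohort missing for individual with unknown parents: %s",
                    ped$id[which((ud | us) & is.na(coh))[1]]))
    lev <- sort(unique(coh[ud | us]))
    labels <- labels %||% paste0("cohort", lev)
    stopifnot(length(labels) == length(lev))
    lab_of <- setNames(labels, lev)
    grp_dam <- ifelse(ud, lab_of[as.character(coh)], NA_character_)
    grp_sire <- ifelse(us, lab_of[as.character(coh)], NA_character_)
  } else { # table
    if (is.null(table)) abort("rule = 'table' needs a table")
    table <- tibble::as_tibble(table)
    if (!"id" %in% names(table)) abort("grouping table needs an 'id' column")
    if ("group" %in% names(table)) {
      table$dam_group <- table$group
      table$sire_group <- table$group
    }
    if (!all(c("dam_group", "sire_group") %in% names(table)))
      abort("grouping table needs 'group' or 'dam_group'/'sire_group' columns")
    m <- match(ped$id, table$id)
    grp_dam <- ifelse(ud, table$dam_group[m], NA_character_)
    grp_sire <- ifelse(us, table$sire_group[m], NA_character_)
    uncovered <- (ud & is.na(grp_dam)) | (us & is.na(grp_sire))
    if (any(uncovered))
      abort(sprintf("unknown-parent slot not covered by grouping table for: %s",
                    paste(head(ped$id[uncovered], 5), collapse = ", ")))
    labels <- labels %||% sort(unique(c(grp_dam, grp_sire)))
    labels <- labels[!is.na(labels)]
    bad <- setdiff(c(grp_dam, grp_sire), c(labels, NA))
    if (length(bad))
      abort(sprintf("group label(s) not in 'labels': %s", paste(bad, collapse = ", ")))
  }

  r <- length(labels)
  dam_m <- matrix(NA_real_, n, r, dimnames = list(ped$id, labels))
  sire_m <- dam_m
  if (any(ud)) dam_m[ud, ] <- t(vapply(grp_dam[ud], unit_vec, numeric(r), labels = labels))
  if (any(us)) sire_m[us, ] <- t(vapply(grp_sire[us], unit_vec, numeric(r), labels = labels))

  reference <- reference %||% labels[1]
  if (!reference %in% labels) abort("reference must be one of the group labels")
  new_grouped_ped(ped, labels, reference, dam_m, sire_m)
}

unit_vec <- function(lab, labels) as.numeric(labels == lab)
isTRUE_vec <- function(x) !is.na(x) & x

new_grouped_ped <- function(ped, labels, reference, dam_m, sire_m) {
  structure(ped,
            gg_groups = labels,
            gg_reference = reference,
            gg_dam_m = dam_m,
            gg_sire_m = sire_m,
            class = c("gg_grouped_ped", class(tibble::as_tibble(ped))))
}

#' @export
#' @method print gg_grouped_ped
print.gg_grouped_ped <- function(x, ...) {
  cat(sprintf("Grouped pedigree: %d individuals, %d genetic group(s) [%s], reference = %s\n",
              nrow(x), length(group_labels(x)),
              paste(group_labels(x), collapse = ", "), reference_group(x)))
  NextMethod()
}

#' Group metadata accessors
#'
#' @param gped a grouped pedigree from [assign_groups()].
#' @return `group_labels()`: character vector of group labels;
#'   `reference_group()`: the reference group label;
#'   `phantom_slots()`: tibble of unknown-parent slots and their membership
#'   vectors (one row per slot, one column per group).
#' @export
group_labels <- function(gped) attr(gped, "gg_groups", exact = TRUE)

#' @rdname group_labels
#' @export
reference_group <- function(gped) attr(gped, "gg_reference", exact = TRUE)

#' @rdname group_labels
#' @export
phantom_slots <- function(gped) {
  check_grouped(gped)
  dam_m <- attr(gped, "gg_dam_m"); sire_m <- attr(gped, "gg_sire_m")
  ud <- is.na(gped$dam); us <- is.na(gped$sire)
  out <- dplyr::bind_rows(
    tibble::tibble(id = gped$id[ud], slot = "dam",
                   tibble::as_tibble(dam_m[ud, , drop = FALSE])),
    tibble::tibble(id = gped$id[us], slot = "sire",
                   tibble::as_tibble(sire_m[us, , drop = FALSE]))
  )
  dplyr::arrange(out, match(.data$id, gped$id), .data$slot)
}

check_grouped <- function(gped) {
  if (!inherits(gped, "gg_grouped_ped"))
    abort("expected a grouped pedigree; call assign_groups() first")
  assert_ordered(gped)
  dam_m <- attr(gped, "gg_dam_m"); sire_m <- attr(gped, "gg_sire_m")
  ud <- is.na(gped$dam); us <- is.na(gped$sire)
  if (any(ud & !stats::complete.cases(dam_m)) ||
      any(us & !stats::complete.cases(sire_m)))
    abort("some unknown-parent slots have no group assignment")
  ok <- function(m, use) {
    if (!any(use)) return(TRUE)
    rs <- rowSums(m[use, , drop = FALSE])
    all(abs(rs - 1) < 1e-12) && all(m[use, ] >= 0)
  }
  if (!ok(dam_m, ud) || !ok(sire_m, us))
    abort("membership vectors must be non-negative and sum to 1")
  invisible(gped)
}

#' Fuzzy phantom-parent classification
#'
#' Replaces hard group assignments of selected phantom-parent slots with
#' membership probability vectors. `table` must have columns `id`, optionally
#' `slot` (`"dam"`, `"sire"` or `"both"`, default both), plus one numeric
#' column per group label. Probabilities must be non-negative and sum to one
#' within `1e-6` per row (no silent renormalization); a hard assignment is the
#' special case of a unit vector.
#'
#' @param gped grouped pedigree.
#' @param table membership table; see Details.
#' @return the grouped pedigree with updated memberships.
#' @export
fuzzy_memberships <- function(gped, table) {
  check_grouped(gped)
  labels <- group_labels(gped)
  table <- tibble::as_tibble(table)
  if (!"id" %in% names(table)) abort("membership table needs an 'id' column")
  if (!all(labels %in% names(table)))
    abort(sprintf("membership table needs one column per group: %s",
                  paste(labels, collapse = ", ")))
  slot <- if ("slot" %in% names(table)) table$slot else rep("both", nrow(table))
  if (!all(slot %in% c("dam", "sire", "both"))) abort("slot must be dam, sire or both")
  m <- as.matrix(table[labels])
  if (any(m < 0)) abort("membership probabilities must be non-negative")
  rs <- rowSums(m)
  if (any(rs == 0)) abort(sprintf("membership row sums to 0 for id %s",
                                  table$id[which(rs == 0)[1]]))
  if (any(abs(rs - 1) > 1e-6))
    abort(sprintf("membership row does not sum to 1 (got %.8f) for id %s",
                  rs[which(abs(rs - 1) > 1e-6)[1]],
                  table$id[which(abs(rs - 1) > 1e-6)[1]]))
  dam_m <- attr(gped, "gg_dam_m"); sire_m <- attr(gped, "gg_sire_m")
  pos <- match(table$id, gped$id)
  if (anyNA(pos))
    abort(sprintf("id not in pedigree: %s", table$id[which(is.na(pos))[1]]))
  for (k in seq_along(pos)) {
    i <- pos[k]
    if (slot[k] %in% c("dam", "both")) {
      if (!is.na(gped$dam[i]))
        abort(sprintf("dam of %s is known; cannot fuzzify that slot", gped$id[i]))
      dam_m[i, ] <- m[k, ]
    }
    if (slot[k] %in% c("sire", "both")) {
      if (!is.na(gped$sire[i]))
        abort(sprintf("sire of %s is known; cannot fuzzify that slot", gped$id[i]))
      sire_m[i, ] <- m[k, ]
    }
  }
  new_grouped_ped(tibble::as_tibble(gped), labels, reference_group(gped), dam_m, sire_m)
}

#' Materialize genetic groups as pseudo-founder rows
#'
#' Returns a plain pedigree in which the `r` genetic groups appear as founder
#' records (ids = group labels) ahead of all individuals, and every
#' hard-assigned unknown-parent slot points at its group id. This is the
#' pedigree on which Henderson's `T` has the group contributions `Q` as its
#' first `r` columns. Errors if any slot has a fuzzy (non-unit) membership,
#' since such a slot has no single pseudo-parent.
#'
#' @param gped grouped pedigree with hard assignments.
#' @return ordered pedigree tibble of r + n records.
#' @export
group_augmented_pedigree <- function(gped) {
  check_grouped(gped)
  labels <- group_labels(gped)
  if (any(labels %in% gped$id))
    abort("group labels clash with individual ids")
  dam_m <- attr(gped, "gg_dam_m"); sire_m <- attr(gped, "gg_sire_m")
  hard_label <- function(mrow) {
    j <- which(mrow == 1)
    if (length(j) != 1) abort("fuzzy membership cannot be materialized as a pseudo-parent")
    labels[j]
  }
  ped <- tibble::as_tibble(gped)[c("id", "dam", "sire")]
  ud <- is.na(ped$dam); us <- is.na(ped$sire)
  ped$dam[ud] <- vapply(which(ud), function(i) hard_label(dam_m[i, ]), character(1))
  ped$sire[us] <- vapply(which(us), function(i) hard_label(sire_m[i, ]), character(1))
  groups <- tibble::tibble(id = labels, dam = NA_character_, sire = NA_character_)
  dplyr::bind_rows(groups, ped)
}
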