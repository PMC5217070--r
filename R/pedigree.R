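#' Coerce a data frame to a pedigree tibble
#'
#' A pedigree is a tibble with character columns `id`, `dam`, `sire`
#' (`NA` = unknown parent) and optional `cohort` (integer), `sex`
#' (`"F"`, `"M"` or `"U"`) and `immigrant` (logical) columns. Parents that are
#' referenced but never appear as rows are appended as founder records, with a
#' warning. Missing-value codes are configurable; by default `"NA"`, `"0"`,
#' `"*"` and the empty string all mean "unknown".
#'
#' A parent slot can be unknown for two reasons: explicitly coded missing, or
#' referencing an identifier absent from the records. Both end up as `NA`
#' (unknown) but are reported distinctly.
#'
#' @param df data frame with at least id/dam/sire columns.
#' @param missing_codes character vector of tokens meaning "unknown parent".
#' @param col_map optional named character vector mapping the standard names
#'   (`id`, `dam`, `sire`, `cohort`, `sex`, `immigrant`) to the column names
#'   used in `df`, e.g. `c(id = "animal", dam = "mother", sire = "father")`.
#' @param quiet suppress informational messages.
#' @return an (unordered) pedigree tibble.
#' @export
as_pedigree <- function(df, missing_codes = c("NA", "0", "*", ""),
                        col_map = NULL, quiet = FALSE) {
  stopifnot(is.data.frame(df), length(missing_codes) > 0)
  df <- tibble::as_tibble(df)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(df))
        abort(sprintf("col_map names column '%s', not present in data", col_map[[std]]))
      names(df)[names(df) == col_map[[std]]] <- std
    }
  }
  need <- c("id", "dam", "sire")
  if (!all(need %in% names(df))) {
    if (ncol(df) >= 3 && is.null(col_map)) {
      names(df)[1:3] <- need
    } else {
      abort("pedigree needs columns id, dam, sire (or a col_map / 3+ columns)")
    }
  }
  to_chr_na <- function(x) {
    x <- trimws(as.character(x))
    x[x %in% missing_codes | is.na(x)] <- NA_character_
    x
  }
  ped <- dplyr::mutate(df,
    id = trimws(as.character(.data$id)),
    dam = to_chr_na(.data$dam),
    sire = to_chr_na(.data$sire)
  )
  if (any(is.na(ped$id) | ped$id == ""))
    abort("empty or missing id")
  dup <- ped$id[duplicated(ped$id)]
  if (length(dup) > 0)
    abort(sprintf("duplicate id %s", paste(unique(dup), collapse = ", ")))
  if (any(ped$id == ped$dam | ped$id == ped$sire, na.rm = TRUE))
    abort("an individual is listed as its own parent")

  if ("cohort" %in% names(ped)) ped$cohort <- as.integer(ped$cohort)
  if ("sex" %in% names(ped)) ped$sex <- as.character(ped$sex)
  if ("immigrant" %in% names(ped)) ped$immigrant <- as.logical(ped$immigrant)

  referenced <- unique(c(ped$dam, ped$sire))
  absent <- setdiff(referenced[!is.na(referenced)], ped$id)
  if (length(absent) > 0) {
    warn(sprintf(
      "%d parent(s) referenced but not recorded; appended as founders: %s",
      length(absent), paste(head(absent, 5), collapse = ", ")))
    add <- tibble::tibble(id = absent, dam = NA_character_, sire = NA_character_)
    for (cl in setdiff(names(ped), names(add))) add[[cl]] <- ped[[cl]][NA_integer_]
    ped <- dplyr::bind_rows(ped, add[names(ped)])
  }
  both <- intersect(ped$dam[!is.na(ped$dam)], ped$sire[!is.na(ped$sire)])
  if (length(both) > 0 && !quiet)
    warn(sprintf("id(s) appearing as both dam and sire (selfing/hermaphrodite or data error?): %s",
                 paste(head(both, 5), collapse = ", ")))
  ped
}

#' Read a pedigree from a delimited text file
#'
#' The file must have a header and at least three columns (id, dam, sire); the
#' separator is auto-detected (comma, tab or semicolon) unless given. Lines
#' starting with `#` are treated as comments.
#'
#' @inheritParams as_pedigree
#' @param path file path.
#' @param sep field separator; `NULL` to auto-detect.
#' @return an (unordered) pedigree tibble; pipe into [order_pedigree()].
#' @export
read_pedigree <- function(path, missing_codes = c("NA", "0", "*", ""),
                          col_map = NULL, sep = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(sep)) {
    l1 <- readLines(path, n = 10L)
    l1 <- l1[!startsWith(l1, "#")][1]
    counts <- vapply(c(",", "\t", ";"), function(s)
      lengths(regmatches(l1, gregexpr(s, l1, fixed = TRUE))), integer(1))
    sep <- c(",", "\t", ";")[which.max(counts)]
    if (max(counts) == 0) abort(sprintf("cannot detect separator in %s", path))
  }
  df <- readr::read_delim(path, delim = sep, comment = "#",
                          col_types = readr::cols(.default = readr::col_character()),
                          na = character(), trim_ws = TRUE,
                          show_col_types = FALSE, progress = FALSE)
  pr <- readr::problems(df)
  if (nrow(pr) > 0)
    abort(sprintf("malformed row at line %d of %s: %s", pr$row[1] + 1L, path,
                  pr$expected[1]))
  if (ncol(df) < 3) abort(sprintf("%s has fewer than 3 columns", path))
  as_pedigree(df, missing_codes = missing_codes, col_map = col_map)
}

#' Write a pedigree to a delimited text file
#'
#' Unknown parents are written as `"NA"`. A provenance comment line is written
#' first; [read_pedigree()] skips it.
#'
#' @param ped pedigree tibble.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, sep = ",") {
  header <- provenance_line("pedigree")
  out <- dplyr::mutate(ped, dplyr::across(dplyr::where(is.character),
                                          ~ ifelse(is.na(.x), "NA", .x)))
  writeLines(header, path)
  readr::write_delim(out, path, delim = sep, na = "NA", append = TRUE,
                     col_names = TRUE)
  invisible(path)
}

provenance_line <- function(what, extra = NULL) {
  v <- as.character(utils::packageVersion("genegroups"))
  paste0("# genegroups ", v, " | ", what,
         if (length(extra)) paste0(" | ", paste(names(extra), extra,
                                                sep = "=", collapse = " ")))
}

# integer parent codes (0 = unknown) for an ordered pedigree
ped_codes <- function(ped) {
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$id
  dam <- unname(pos[ped$dam]); dam[is.na(dam)] <- 0L
  sire <- unname(pos[ped$sire]); sire[is.na(sire)] <- 0L
  list(dam = as.integer(dam), sire = as.integer(sire))
}

ped_is_ordered <- function(ped) {
  cd <- ped_codes(ped)
  all(cd$dam < seq_len(nrow(ped))) && all(cd$sire < seq_len(nrow(ped)))
}

assert_ordered <- function(ped) {
  if (!all(c("id", "dam", "sire") %in% names(ped)))
    abort("not a pedigree: needs columns id, dam, sire")
  if (!ped_is_ordered(ped))
    abort("pedigree is not ordered; call order_pedigree() first")
  invisible(ped)
}

#' Validate and topologically order a pedigree
#'
#' Reorders records so that every parent precedes its offspring. The sort is
#' stable: whenever several records are eligible, the earliest in input order
#' is placed first, so an already-ordered pedigree is returned unchanged.
#' Errors if the pedigree contains a cycle (an individual its own ancestor).
#'
#' @param ped pedigree tibble (see [as_pedigree()]).
#' @return the same records, ordered.
#' @export
order_pedigree <- function(ped) {
  ped <- as_pedigree(ped, quiet = TRUE)
  n <- nrow(ped)
  if (ped_is_ordered(ped)) return(ped)
  pos <- seq_len(n); names(pos) <- ped$id
  dam <- unname(pos[ped$dam]); sire <- unname(pos[ped$sire])
  placed <- logical(n)
  ready <- is.na(dam) & is.na(sire)
  # parents-placed counter per record
  need <- (!is.na(dam)) + (!is.na(sire))
  children <- split(rep(seq_len(n), 2L), c(dam, sire))
  out <- integer(n)
  for (k in seq_len(n)) {
    idx <- which(ready & !placed)
    if (length(idx) == 0) {
      cyc <- find_cycle(dam, sire, placed)
      abort(sprintf("pedigree contains a cycle: %s",
                    paste(ped$id[cyc], collapse = " -> ")))
    }
    j <- idx[1]
    placed[j] <- TRUE
    out[k] <- j
    for (ch in children[[as.character(j)]]) {
      need[ch] <- need[ch] - 1L
      if (need[ch] == 0L) ready[ch] <- TRUE
    }
  }
  ped[out, ]
}

find_cycle <- function(dam, sire, placed) {
  start <- which(!placed)[1]
  seen <- integer(0)
  cur <- start
  repeat {
    seen <- c(seen, cur)
    nxt <- c(dam[cur], sire[cur])
    nxt <- nxt[!is.na(nxt) & !placed[nxt]]
    if (length(nxt) == 0) return(seen)  # should not happen when a cycle exists
    cur <- nxt[1]
    hit <- which(seen == cur)
    if (length(hit)) return(c(seen[hit:length(seen)], cur))
  }
}

#' Summarize missing parentage in a pedigree
#'
#' Counts and percentages of unknown dams and sires, founders (both parents
#' unknown) and non-founders with at least one unknown parent — the statistics
#' commonly reported when describing how incomplete a study pedigree is.
#'
#' @param ped pedigree tibble.
#' @return a one-row tibble with columns `n_total`, `n_unknown_dam`,
#'   `n_unknown_sire`, `pct_unknown_dam`, `pct_unknown_sire`, `n_founders`,
#'   `n_nonfounder_unknown`.
#' @export
missingness_summary <- function(ped) {
  ud <- is.na(ped$dam); us <- is.na(ped$sire)
  n <- nrow(ped)
  tibble::tibble(
    n_total = n,
    n_unknown_dam = sum(ud),
    n_unknown_sire = sum(us),
    pct_unknown_dam = 100 * sum(ud) / n,
    pct_unknown_sire = 100 * sum(us) / n,
    n_founders = sum(ud & us),
    n_nonfounder_unknown = sum((ud | us) & !(ud & us))
  )
}
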