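#' Construct a pedigree object
#'
#' A pedigree is a data frame with one row per animal and a fixed column
#' contract: `id`, `sire`, `dam`, `sex`, `generation`, and optionally
#' `line`, `family` and phenotype columns (`best_distance_m`,
#' `body_weight_g`, `work_J`). Unknown parents are coded `NA` (the tokens
#' `"0"` and `""` are normalized to `NA` on input). Row order of the input
#' is preserved; computations that require a topological order sort
#' internally.
#'
#' @param df data frame with at least columns `id`, `sire`, `dam`, `sex`,
#'   `generation`.
#' @param validate if `TRUE` (default), run [validate_pedigree()] and stop
#'   on any error-severity issue.
#' @return An object of class `pedigree` (a classed data frame).
#' @export
pedigree <- function(df, validate = TRUE) {
  stopifnot(is.data.frame(df))
  required <- c("id", "sire", "dam", "sex", "generation")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("pedigree is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df$id <- as.character(df$id)
  df$sire <- normalize_parent(df$sire)
  df$dam <- normalize_parent(df$dam)
  df$sex <- toupper(as.character(df$sex))
  df$generation <- as.integer(df$generation)
  if (!"line" %in% names(df)) df[["line"]] <- rep(NA_character_, nrow(df))
  if (!"family" %in% names(df)) df[["family"]] <- rep(NA_integer_, nrow(df))
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  if (validate) {
    issues <- validate_pedigree(df)
    bad <- issues[issues$severity == "error", , drop = FALSE]
    if (nrow(bad))
      stop("invalid pedigree:\n",
           paste(sprintf("  [%s] %s: %s", bad$severity, bad$rule, bad$id),
                 collapse = "\n"))
  }
  df
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "0" | x == "" | toupper(x) == "UNKNOWN")] <- NA_character_
  x
}

#' Read a pedigree from a delimited file
#'
#' Reads a one-row-per-animal table (CSV by default) and returns a
#' validated [pedigree()]. A `dialect` mapping translates arbitrary column
#' headers onto the pedigree column contract, so supplementary-style
#' pedigree exports can be ingested without editing the file.
#'
#' @param path file path.
#' @param dialect named character vector mapping pedigree fields to column
#'   names in the file, e.g. `c(id = "Animal", sire = "Father", ...)`.
#'   Fields absent from the mapping are looked up under their own names.
#' @param sep field separator (default `","`).
#' @return A [pedigree()] object. Unresolvable parent references, duplicate
#'   ids and sex-inconsistent parents are hard errors.
#' @export
read_pedigree <- function(path, dialect = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (!is.null(dialect)) {
    for (field in names(dialect)) {
      src <- dialect[[field]]
      if (!src %in% names(raw))
        stop("dialect maps '", field, "' to missing column '", src, "'")
      names(raw)[names(raw) == src] <- field
    }
  }
  if (nrow(raw) == 0) {
    empty <- data.frame(id = character(), sire = character(),
                        dam = character(), sex = character(),
                        generation = integer(), stringsAsFactors = FALSE)
    return(pedigree(empty))
  }
  for (col in intersect(c("generation", "family"), names(raw)))
    raw[[col]] <- as.integer(raw[[col]])
  for (col in intersect(c("best_distance_m", "body_weight_g", "work_J"),
                        names(raw)))
    raw[[col]] <- as.numeric(raw[[col]])
  pedigree(raw)
}

#' Write a pedigree to CSV
#'
#' Inverse of [read_pedigree()]: unknown parents are written as `0`.
#'
#' @param ped a [pedigree()].
#' @param path output file path.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Report structural issues in a pedigree
#'
#' Non-erroring check of the pedigree invariants. Rules covered:
#' `duplicate_id`, `orphan_parent` (a parent id that resolves to no row),
#' `sex_mismatch` (a sire recorded with sex F, or dam with sex M),
#' `generation_inversion` (parent generation not less than offspring
#' generation; warning severity, since real colonies contain
#' cross-generation matings), and `cycle` (an animal is its own ancestor).
#'
#' @param ped a pedigree-shaped data frame.
#' @return data frame with columns `severity` (`"error"`/`"warning"`),
#'   `rule`, `id`; zero rows when the pedigree is clean.
#' @export
validate_pedigree <- function(ped) {
  issues <- list()
  add <- function(severity, rule, ids) {
    if (length(ids))
      issues[[length(issues) + 1L]] <<-
        data.frame(severity = severity, rule = rule, id = as.character(ids),
                   stringsAsFactors = FALSE)
  }
  dup <- unique(ped$id[duplicated(ped$id)])
  add("error", "duplicate_id", dup)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  add("error", "orphan_parent",
      ped$id[(!is.na(ped$sire) & is.na(si)) | (!is.na(ped$dam) & is.na(di))])
  bad_sire <- !is.na(si) & ped$sex[si] != "M"
  bad_dam <- !is.na(di) & ped$sex[di] != "F"
  add("error", "sex_mismatch", unique(c(ped$sire[bad_sire], ped$dam[bad_dam])))
  if (!length(dup)) {
    inv <- (!is.na(si) & ped$generation[si] >= ped$generation) |
           (!is.na(di) & ped$generation[di] >= ped$generation)
    add("warning", "generation_inversion", ped$id[inv & !is.na(inv)])
    cyc <- find_cycles(si, di)
    add("error", "cycle", ped$id[cyc])
  }
  if (!length(issues))
    return(data.frame(severity = character(), rule = character(),
                      id = character(), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

## depth-first reachability: TRUE for rows lying on a parentage cycle
find_cycles <- function(si, di) {
  n <- length(si)
  state <- integer(n) # 0 unvisited, 1 on stack, 2 done
  on_cycle <- logical(n)
  for (root in seq_len(n)) {
    if (state[root] != 0L) next
    stack <- root
    while (length(stack)) {
      v <- stack[length(stack)]
      if (state[v] == 0L) {
        state[v] <- 1L
        for (p in c(si[v], di[v])) {
          if (is.na(p)) next
          if (state[p] == 1L) on_cycle[p] <- TRUE
          else if (state[p] == 0L) stack <- c(stack, p)
        }
      } else {
        state[v] <- 2L
        stack <- stack[-length(stack)]
      }
    }
  }
  on_cycle
}

#' Founder subset of a pedigree
#'
#' Founders are animals with both parents unknown.
#'
#' @param ped a [pedigree()].
#' @return logical vector marking founder rows.
#' @export
is_founder <- function(ped) is.na(ped$sire) & is.na(ped$dam)

#' Topological order of a pedigree
#'
#' Returns a permutation of row indices in which every parent precedes all
#' of its offspring (Kahn's algorithm). Errors if the parentage graph is
#' cyclic.
#'
#' @param ped a [pedigree()].
#' @return integer vector of row indices.
#' @export
topological_order <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in unique(stats::na.omit(c(si[i], di[i])))) {
      indeg[i] <- indeg[i] + 1L
      children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) != n)
    stop("pedigree parentage graph is cyclic; no topological order exists")
  ord
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d animals, %d founders, generations %s-%s\n",
              nrow(x), sum(is_founder(x)),
              if (nrow(x)) min(x$generation) else "-",
              if (nrow(x)) max(x$generation) else "-"))
  lines <- unique(stats::na.omit(x$line))
  if (length(lines)) cat("Lines:", paste(lines, collapse = ", "), "\n")
  if (nrow(x)) {
    cat("\n")
    print(utils::head(as.data.frame(x), 6L))
    if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.pedigree <- function(object, ...) {
  tab <- as.data.frame(table(generation = object$generation,
                             sex = object$sex))
  tab <- tab[tab$Freq > 0, ]
  structure(list(n = nrow(object), n_founders = sum(is_founder(object)),
                 by_generation_sex = tab),
            class = "summary.pedigree")
}

#' @export
print.summary.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree with %d animals (%d founders)\n", x$n, x$n_founders))
  print(x$by_generation_sex, row.names = FALSE)
  invisible(x)
}

#' Count animals by line and generation
#'
#' @param ped a [pedigree()].
#' @return data frame with columns `line`, `generation`, `n`.
#' @export
count_animals <- function(ped) {
  key <- interaction(ped$line, ped$generation, drop = TRUE)
  agg <- as.data.frame(table(key))
  parts <- do.call(rbind, strsplit(as.character(agg$key), ".", fixed = TRUE))
  data.frame(line = parts[, 1], generation = as.integer(parts[, 2]),
             n = agg$Freq, stringsAsFactors = FALSE)
}
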