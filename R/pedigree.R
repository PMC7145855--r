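#' Build a validated twin pedigree from tabular records
#'
#' Validates a table of individual records (twins grouped by `pair_id`,
#' singletons standing alone) and returns a `pedigree` object, the entry
#' point for the polygenic machinery. The design covers extended-twin
#' cohorts: monozygotic (MZ) and dizygotic (DZ) twin pairs, full-sibling
#' groups, and unrelated singletons, all nested in families.
#'
#' Degenerate "pair" groups of size one (a twin whose co-twin is absent)
#' are demoted to singletons with a warning rather than rejected, so
#' real-world pedigree tables with dropped individuals still load.
#'
#' @param records A data frame with columns `id`, `family_id`, `zygosity`
#'   (one of `"MZ"`, `"DZ"`, `"SIB"`, `"NONE"`), `sex` (coded 0/1), `age`
#'   (years), and optionally `pair_id` (empty or `NA` for singletons).
#' @return A `pedigree`: a tibble of the validated records (input order
#'   preserved) with class `"pedigree"`.
#' @examples
#' ped <- build_pedigree(data.frame(
#'   id = c("a", "b"), family_id = "f1", pair_id = "p1",
#'   zygosity = "MZ", sex = c(0, 1), age = c(30, 30)
#' ))
#' expected_relatedness(ped)
#' @export
build_pedigree <- function(records) {
  records <- tibble::as_tibble(records)
  required <- c("id", "family_id", "zygosity", "sex", "age")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("pedigree records lack required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"pair_id" %in% names(records)) records$pair_id <- ""
  records$id <- as.character(records$id)
  records$family_id <- as.character(records$family_id)
  records$pair_id <- ifelse(is.na(records$pair_id), "", as.character(records$pair_id))
  records$zygosity <- as.character(records$zygosity)

  if (anyDuplicated(records$id)) {
    dup <- unique(records$id[duplicated(records$id)])
    abort(paste0("duplicate individual id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  allowed <- c("MZ", "DZ", "SIB", "NONE")
  bad <- setdiff(unique(records$zygosity), allowed)
  if (length(bad) > 0) {
    abort(paste0("unknown zygosity label(s): ", paste(bad, collapse = ", ")))
  }
  if (!all(records$sex %in% c(0, 1))) {
    abort("sex must be coded 0/1")
  }

  grouped <- records$zygosity != "NONE" & records$pair_id != ""
  if (any(records$zygosity != "NONE" & records$pair_id == "")) {
    warn("individuals with MZ/DZ/SIB zygosity but empty pair_id demoted to singletons")
    records$zygosity[records$zygosity != "NONE" & records$pair_id == ""] <- "NONE"
    grouped <- records$zygosity != "NONE" & records$pair_id != ""
  }

  if (any(grouped)) {
    grp <- records[grouped, ]
    # a pair group must live inside one family and carry one zygosity label
    by_pair <- split(seq_len(nrow(grp)), grp$pair_id)
    singles <- character(0)
    for (pid in names(by_pair)) {
      idx <- by_pair[[pid]]
      if (length(unique(grp$family_id[idx])) > 1) {
        abort(paste0("pair_id '", pid, "' spans more than one family"))
      }
      if (length(unique(grp$zygosity[idx])) > 1) {
        abort(paste0("pair_id '", pid, "' mixes zygosity labels"))
      }
      if (length(idx) < 2) singles <- c(singles, pid)
    }
    if (length(singles) > 0) {
      warn(paste0("pair group(s) of size 1 demoted to singletons: ",
                  paste(head(singles, 5), collapse = ", ")))
      demote <- records$pair_id %in% singles
      records$zygosity[demote] <- "NONE"
      records$pair_id[demote] <- ""
    }
  }

  structure(records, class = c("pedigree", class(records)))
}

#' Read a pedigree from CSV
#'
#' Expects header `id,family_id,pair_id,zygosity,sex,age` (UTF-8, zygosity
#' in MZ/DZ/SIB/NONE, empty `pair_id` for singletons).
#'
#' @param path Path to a CSV file.
#' @return A [build_pedigree()] `pedigree`.
#' @export
read_pedigree <- function(path) {
  build_pedigree(readr::read_csv(path, show_col_types = FALSE,
                                 col_types = readr::cols(
                                   id = "c", family_id = "c", pair_id = "c",
                                   zygosity = "c", sex = "d", age = "d")))
}

#' Expected additive-genetic relatedness matrix of a pedigree
#'
#' Returns the classical twin-design covariance kernel on the 2*Phi scale:
#' 1 on the diagonal, 1 between MZ co-twins, 0.5 between DZ co-twins and
#' full siblings, and 0 otherwise (including co-familial individuals that
#' are not in a common MZ/DZ/SIB group). This expected-kinship kernel is
#' what the polygenic model uses as the genetic covariance structure.
#'
#' @param pedigree A `pedigree` from [build_pedigree()].
#' @return An n x n symmetric matrix with individual ids as dimnames and
#'   class `"relatedness_matrix"`.
#' @export
expected_relatedness <- function(pedigree) {
  stopifnot(inherits(pedigree, "pedigree"))
  n <- nrow(pedigree)
  K <- diag(1, n)
  grouped <- which(pedigree$zygosity != "NONE" & pedigree$pair_id != "")
  if (length(grouped) > 0) {
    for (idx in split(grouped, pedigree$pair_id[grouped])) {
      r <- if (pedigree$zygosity[idx[1]] == "MZ") 1.0 else 0.5
      K[idx, idx] <- r
    }
    diag(K) <- 1
  }
  dimnames(K) <- list(pedigree$id, pedigree$id)
  class(K) <- c("relatedness_matrix", class(K))
  K
}

#' Partition a pedigree into independent family blocks
#'
#' Blocks are the maximal sets of individuals connected by nonzero expected
#' relatedness; relatedness is exactly zero across blocks, so the polygenic
#' likelihood factorizes over them.
#'
#' @param pedigree A `pedigree`.
#' @return A list of integer index vectors (into the pedigree rows) covering
#'   all individuals.
#' @export
family_blocks <- function(pedigree) {
  stopifnot(inherits(pedigree, "pedigree"))
  n <- nrow(pedigree)
  grouped <- pedigree$zygosity != "NONE" & pedigree$pair_id != ""
  key <- ifelse(grouped, paste0("g:", pedigree$pair_id), paste0("i:", seq_len(n)))
  idx <- split(seq_len(n), factor(key, levels = unique(key)))
  unname(idx)
}

# blocks straight from a relatedness matrix (used after row subsetting)
blocks_from_matrix <- function(K) {
  n <- nrow(K)
  seen <- logical(n)
  blocks <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    # one BFS sweep; families are tiny so this stays cheap
    blk <- i
    frontier <- i
    seen[i] <- TRUE
    while (length(frontier) > 0) {
      nb <- which(colSums(abs(K[frontier, , drop = FALSE])) > 0 & !seen)
      seen[nb] <- TRUE
      blk <- c(blk, nb)
      frontier <- nb
    }
    blocks[[length(blocks) + 1]] <- sort(blk)
  }
  blocks
}

#' @export
print.pedigree <- function(x, ...) {
  zy <- table(factor(x$zygosity, levels = c("MZ", "DZ", "SIB", "NONE")))
  cat(sprintf("<pedigree> %d individuals in %d families (%d MZ, %d DZ, %d SIB, %d singletons)\n",
              nrow(x), length(unique(x$family_id)),
              zy[["MZ"]], zy[["DZ"]], zy[["SIB"]], zy[["NONE"]]))
  NextMethod()
}
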