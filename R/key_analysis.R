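# Set and multiset algebra over key vectors: similarity measures,
# distinct/total counts, common and specific keys, Venn regions.

check_comparable <- function(a, b) {
  stopifnot(inherits(a, "tsr_keyvector"), inherits(b, "tsr_keyvector"))
  if (!identical(a$mode, b$mode) ||
      !identical(a$config_hash, b$config_hash)) {
    stop("key vectors are not comparable: mode/config mismatch",
         call. = FALSE)
  }
}

#' Generalized Jaccard similarity of two key vectors
#'
#' Frequency-aware multiset similarity
#' `sum_k min(f_a(k), f_b(k)) / sum_k max(f_a(k), f_b(k))`:
#' 1 for identical vectors, 0 for disjoint key supports.
#'
#' @param a,b `tsr_keyvector` objects under the same configuration.
#' @return Similarity in `[0, 1]`.
#' @export
generalized_jaccard <- function(a, b) {
  check_comparable(a, b)
  keys <- union(names(a$counts), names(b$counts))
  fa <- fb <- stats::setNames(numeric(length(keys)), keys)
  fa[names(a$counts)] <- a$counts
  fb[names(b$counts)] <- b$counts
  sum(pmin(fa, fb)) / sum(pmax(fa, fb))
}

#' Normalized Jaccard similarity of two key vectors
#'
#' Frequency-free set Jaccard over the key supports:
#' `|support(a) n support(b)| / |support(a) u support(b)|`.  Used for
#' single amino-acid comparisons, where occurrence frequencies are
#' small and dominated by the residue's own atom count.
#'
#' @inheritParams generalized_jaccard
#' @return Similarity in `[0, 1]`.
#' @export
normalized_jaccard <- function(a, b) {
  check_comparable(a, b)
  sa <- names(a$counts)
  sb <- names(b$counts)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

#' Distinct and total key counts
#'
#' @param kv A `tsr_keyvector`.
#' @return Named numeric vector `c(distinct = , total = )`: the support
#'   size and the frequency sum (= retained triangle count).
#' @export
count_keys <- function(kv) {
  stopifnot(inherits(kv, "tsr_keyvector"))
  if (length(kv$counts) == 0) stop("empty key vector", call. = FALSE)
  c(distinct = length(kv$counts), total = sum(kv$counts))
}

#' Group several key vectors under a name
#'
#' @param name Group label (e.g. `"P700"`, `"PsaA"`).
#' @param members List of `tsr_keyvector` objects sharing one
#'   configuration.
#' @return Object of class `tsr_keygroup`.
#' @export
key_group <- function(name, members) {
  stopifnot(is.character(name), length(members) >= 1)
  for (m in members[-1]) check_comparable(members[[1]], m)
  structure(list(name = name, members = members), class = "tsr_keygroup")
}

#' Common keys of a group
#'
#' Distinct common keys are those present in every member.  Each member's
#' total common count sums its own frequencies over that shared support.
#'
#' @param group A `tsr_keygroup`.
#' @return List with `distinct_common` (character key set),
#'   `n_distinct_common`, `per_member_total` (named numeric),
#'   `mean_total_common`, `sd_total_common`.
#' @export
common_keys <- function(group) {
  stopifnot(inherits(group, "tsr_keygroup"))
  supports <- lapply(group$members, function(kv) names(kv$counts))
  common <- Reduce(intersect, supports)
  totals <- vapply(group$members, function(kv) {
    sum(kv$counts[names(kv$counts) %in% common])
  }, numeric(1))
  names(totals) <- vapply(seq_along(group$members), function(i) {
    role <- group$members[[i]]$provenance$role
    if (is.null(role)) paste0(group$name, "_", i) else role
  }, character(1))
  list(distinct_common = sort_keys(common),
       n_distinct_common = length(common),
       per_member_total = totals,
       mean_total_common = mean(totals),
       sd_total_common = if (length(totals) > 1) stats::sd(totals) else 0)
}

#' Keys specific to one group against contrast groups
#'
#' A specific key is present in every member of `target` and absent from
#' every member of every group in `others`.
#'
#' @param target A `tsr_keygroup`.
#' @param others List of contrast `tsr_keygroup` objects.
#' @return Character vector of specific keys (sorted numerically).
#' @export
specific_keys <- function(target, others) {
  stopifnot(inherits(target, "tsr_keygroup"))
  if (inherits(others, "tsr_keygroup")) others <- list(others)
  common <- common_keys(target)$distinct_common
  other_support <- unique(unlist(lapply(others, function(g) {
    unlist(lapply(g$members, function(kv) names(kv$counts)))
  })))
  sort_keys(setdiff(common, other_support))
}

sort_keys <- function(keys) {
  if (length(keys) == 0) return(character(0))
  keys[order(as.numeric(keys))]
}

#' Venn region cardinalities over key groups
#'
#' Computes, for every non-empty subset of groups, the number of distinct
#' keys found in exactly those groups.  At `level = "group-union"` a
#' group's support pools (unions) its members' supports; at
#' `level = "all-members"` a key belongs to a group only if every member
#' carries it.
#'
#' @param groups List of `tsr_keygroup` objects.
#' @param level `"group-union"` or `"all-members"`.
#' @return Named integer vector; names are `&`-joined group names.
#'   Cardinalities sum to the size of the union of all supports
#'   (`group-union` level).
#' @export
venn_regions <- function(groups, level = c("group-union", "all-members")) {
  level <- match.arg(level)
  stopifnot(length(groups) >= 2)
  supports <- lapply(groups, function(g) {
    sets <- lapply(g$members, function(kv) names(kv$counts))
    if (level == "group-union") Reduce(union, sets)
    else Reduce(intersect, sets)
  })
  names(supports) <- vapply(groups, function(g) g$name, character(1))
  all_keys <- unique(unlist(supports))
  membership <- vapply(supports, function(s) all_keys %in% s,
                       logical(length(all_keys)))
  if (length(all_keys) == 1) membership <- matrix(membership, nrow = 1)
  g <- length(groups)
  region <- apply(membership, 1, function(row) {
    paste(names(supports)[row], collapse = "&")
  })
  counts <- table(region)
  # report every 2^g - 1 region, zero-filled, in subset order
  subsets <- unlist(lapply(seq_len(g), function(k) {
    combn(names(supports), k, FUN = paste, collapse = "&")
  }))
  out <- stats::setNames(integer(length(subsets)), subsets)
  out[names(counts)] <- as.integer(counts)
  out
}

#' Pairwise similarity matrix of key vectors
#'
#' @param members List of `tsr_keyvector` objects (one configuration).
#' @param measure `"generalized"` (frequency-aware) or `"normalized"`
#'   (set Jaccard).
#' @param labels Optional row/column labels; defaults to member roles.
#' @return Symmetric matrix with unit diagonal, class `tsr_similarity`,
#'   with `measure` and `config_hash` attributes.
#' @export
similarity_matrix <- function(members,
                              measure = c("generalized", "normalized"),
                              labels = NULL) {
  measure <- match.arg(measure)
  n <- length(members)
  stopifnot(n >= 2)
  fun <- if (measure == "generalized") generalized_jaccard
         else normalized_jaccard
  if (is.null(labels)) {
    labels <- vapply(seq_len(n), function(i) {
      role <- members[[i]]$provenance$role
      if (is.null(role)) paste0("m", i) else
        paste(members[[i]]$provenance$source_id, role, sep = ":")
    }, character(1))
  }
  labels <- make.unique(labels)
  S <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      S[i, j] <- S[j, i] <- fun(members[[i]], members[[j]])
    }
  }
  dimnames(S) <- list(labels, labels)
  attr(S, "measure") <- measure
  attr(S, "config_hash") <- members[[1]]$config_hash
  class(S) <- c("tsr_similarity", class(S))
  S
}

#' Distance matrix from a similarity matrix
#'
#' Elementwise `1 - similarity`.
#'
#' @param S Similarity matrix in `[0, 1]`.
#' @return Distance matrix with zero diagonal.
#' @export
to_distance <- function(S) {
  D <- 1 - unclass(S)
  attr(D, "measure") <- attr(S, "measure")
  D
}
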