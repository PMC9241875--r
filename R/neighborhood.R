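SCATTERED_CRT <- c("crtE", "crtG", "crtZ", "crtW", "DUF2141")

# features come in as a data.frame; normalize and validate
as_features <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("gene_id", "name", "contig", "start", "end", "strand")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) stop("feature table lacks column(s): ",
                             paste(miss, collapse = ", "))
  if (nrow(x) == 0) stop("annotation is empty")
  if (any(x$start > x$end)) stop("feature with start > end")
  if (!all(x$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  x[order(x$contig, x$start), , drop = FALSE]
}

match_name <- function(names, targets) {
  tolower(names) %in% tolower(targets)
}

#' Detect the carotenoid gene cluster and build its signature
#'
#' Finds the maximal run of target-named genes on one contig whose
#' successive intergenic gaps stay within `max_gap` — the
#' `crtB`-`log`-`crtI`(-`hyp`)-`crtY` cluster in the default configuration —
#' and records genome-wide presence of the scattered carotenoid genes
#' (`crtE`, `crtG`, `crtZ`, `crtW`, `DUF2141`) plus the two diagnostic
#' adjacencies tested under the same gap rule: `crtW` immediately upstream
#' of `crtZ` (relative to `crtZ`'s strand) and the `crtG`-`DUF2141`
#' colocation.
#'
#' The cluster is canonicalized by majority strand: a cluster lying on the
#' minus strand is reported in reversed order with flipped strands, so the
#' signature is invariant under reverse-complementing the contig.
#'
#' @param annotation `data.frame` of gene features (`gene_id`, `name`,
#'   `contig`, `start`, `end`, `strand`; 1-based inclusive coordinates),
#'   e.g. from [read_features_gff3()] or [gen_crt_annotation()].
#' @param target_names cluster gene names (matched case-insensitively).
#' @param max_gap maximum intergenic gap (bases) within the cluster and for
#'   adjacency calls.
#' @return An object of class `crt_signature`: `cluster_members`
#'   (`data.frame` `name`, `strand`, in canonical order), `adjacencies`
#'   (character vector `"a>b"` of ordered adjacent pairs),
#'   `scattered_presence` (named logical).  If no target gene is present the
#'   signature is empty, not an error.
#' @export
detect_crt_cluster <- function(annotation,
                               target_names = c("crtB", "log", "crtI",
                                                "hyp", "crtY"),
                               max_gap = 500) {
  feats <- as_features(annotation)
  targets <- feats[match_name(feats$name, target_names), , drop = FALSE]

  cluster <- targets[0, ]
  if (nrow(targets) > 0) {
    runs <- list()
    for (ctg in unique(targets$contig)) {
      tf <- targets[targets$contig == ctg, , drop = FALSE]
      brk <- c(TRUE, tf$start[-1] - tf$end[-nrow(tf)] - 1L > max_gap)
      run_id <- cumsum(brk)
      runs <- c(runs, split(tf, run_id))
    }
    sizes <- vapply(runs, nrow, 0L)
    best <- which(sizes == max(sizes))
    starts <- vapply(runs[best], function(r) r$start[1], 0)
    cluster <- runs[[best[order(starts)[1]]]]      # longest run, leftmost tie
  }

  # canonical orientation: majority minus strand -> flip
  if (nrow(cluster) > 0 && mean(cluster$strand == "-") > 0.5) {
    cluster <- cluster[rev(seq_len(nrow(cluster))), , drop = FALSE]
    cluster$strand <- ifelse(cluster$strand == "-", "+", "-")
  }
  members <- data.frame(name = cluster$name, strand = cluster$strand,
                        row.names = NULL)
  adjacencies <- character(0)
  if (nrow(members) > 1) {
    adjacencies <- paste(members$name[-nrow(members)], members$name[-1],
                         sep = ">")
  }

  # genome-wide presence of the scattered crt genes, plus any cluster gene
  # that exists in the annotation but fell outside the detected cluster
  stray <- setdiff(tolower(targets$name), tolower(cluster$name))
  stray_names <- target_names[tolower(target_names) %in% stray]
  scattered <- vapply(c(SCATTERED_CRT, stray_names),
                      function(nm) any(match_name(feats$name, nm)),
                      logical(1))

  if (adjacent_upstream(feats, "crtW", "crtZ", max_gap)) {
    adjacencies <- c(adjacencies, "crtW>crtZ")
  }
  if (colocated(feats, "crtG", "DUF2141", max_gap)) {
    adjacencies <- c(adjacencies, "crtG>DUF2141")
  }

  structure(list(cluster_members = members,
                 adjacencies = unique(adjacencies),
                 scattered_presence = scattered,
                 max_gap = max_gap),
            class = "crt_signature")
}

# a immediately upstream of b, relative to b's strand, gap <= max_gap
adjacent_upstream <- function(feats, a, b, max_gap) {
  fa <- feats[match_name(feats$name, a), , drop = FALSE]
  fb <- feats[match_name(feats$name, b), , drop = FALSE]
  for (i in seq_len(nrow(fa))) {
    for (j in seq_len(nrow(fb))) {
      if (fa$contig[i] != fb$contig[j]) next
      if (fb$strand[j] == "+") {
        gap <- fb$start[j] - fa$end[i] - 1L
        if (gap >= 0 && gap <= max_gap) return(TRUE)
      } else {
        gap <- fa$start[i] - fb$end[j] - 1L
        if (gap >= 0 && gap <= max_gap) return(TRUE)
      }
    }
  }
  FALSE
}

# orientation-free colocation within max_gap
colocated <- function(feats, a, b, max_gap) {
  fa <- feats[match_name(feats$name, a), , drop = FALSE]
  fb <- feats[match_name(feats$name, b), , drop = FALSE]
  for (i in seq_len(nrow(fa))) {
    for (j in seq_len(nrow(fb))) {
      if (fa$contig[i] != fb$contig[j]) next
      gap <- max(fa$start[i], fb$start[j]) - min(fa$end[i], fb$end[j]) - 1L
      if (gap <= max_gap) return(TRUE)
    }
  }
  FALSE
}

#' @export
print.crt_signature <- function(x, ...) {
  if (nrow(x$cluster_members) == 0) {
    cat("crt signature: no cluster detected\n")
  } else {
    cat("crt cluster:",
        paste(sprintf("%s(%s)", x$cluster_members$name,
                      x$cluster_members$strand), collapse = " - "), "\n")
  }
  cat("scattered:",
      paste(names(x$scattered_presence)[x$scattered_presence],
            collapse = ", "), "\n")
  if (length(x$adjacencies) > 0) {
    cat("adjacencies:", paste(x$adjacencies, collapse = ", "), "\n")
  }
  invisible(x)
}

sig_present <- function(sig, name) {
  if (tolower(name) %in% tolower(sig$cluster_members$name)) return(TRUE)
  hit <- match(tolower(name), tolower(names(sig$scattered_presence)))
  !is.na(hit) && isTRUE(sig$scattered_presence[[hit]])
}

#' Load an arrangement rule table
#'
#' Rules are an ordered YAML list; each rule has a `label` and any of
#' `require_present`, `require_absent` (gene names) and `require_adjacent`
#' (pairs `[a, b]`, matched against the signature's ordered adjacencies).
#' The first matching rule wins.  The shipped default table encodes the
#' four arrangement types I-IV by the presence of `hyp` in the cluster and
#' of `crtW` with its `crtZ` adjacency; it is deliberately editable, since
#' arrangement typing conventions differ between studies.
#'
#' @param path YAML file; default: the table shipped with the package.
#' @return list of validated rules.
#' @export
load_crt_rules <- function(path = system.file("extdata", "crt_rules.yaml",
                                              package = "panogri")) {
  raw <- yaml::read_yaml(path)
  rules <- raw$rules
  if (is.null(rules) || length(rules) == 0) {
    stop("rule config error: no `rules` list in ", path)
  }
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    if (is.null(r$label)) stop("rule config error: rule ", i, " lacks a label")
    for (adj in r$require_adjacent %||% list()) {
      if (length(adj) != 2) {
        stop("rule config error: adjacency in rule '", r$label,
             "' must be a pair")
      }
    }
  }
  rules
}

#' Assign an arrangement type to a crt signature
#'
#' Applies the ordered rule table; the first rule whose required presences,
#' absences and adjacencies all hold gives the label.  When no rule
#' matches, `"untyped"` is returned with the per-rule failed predicates in
#' the `unmatched` attribute.
#'
#' @param sig a [detect_crt_cluster()] signature.
#' @param rules rule table from [load_crt_rules()].
#' @return the type label (character scalar).
#' @export
assign_arrangement_type <- function(sig, rules = load_crt_rules()) {
  stopifnot(inherits(sig, "crt_signature"))
  failures <- list()
  for (r in rules) {
    fails <- character(0)
    for (nm in r$require_present %||% character(0)) {
      if (!sig_present(sig, nm)) fails <- c(fails, paste0("present:", nm))
    }
    for (nm in r$require_absent %||% character(0)) {
      if (sig_present(sig, nm)) fails <- c(fails, paste0("absent:", nm))
    }
    for (adj in r$require_adjacent %||% list()) {
      key <- paste(adj[[1]], adj[[2]], sep = ">")
      if (!key %in% sig$adjacencies) fails <- c(fails, paste0("adjacent:", key))
    }
    if (length(fails) == 0) return(r$label)
    failures[[r$label]] <- fails
  }
  structure("untyped", unmatched = failures)
}

#' Simulate an annotated carotenoid gene neighborhood
#'
#' Builds a single-contig annotation with the contiguous
#' `crtB`-`log`-`crtI`(-`hyp`)-`crtY` cluster (intergenic gaps below
#' `max_gap`) plus the scattered `crtE`, `crtG`+`DUF2141` and `crtZ`
#' (with `crtW` immediately upstream when the arrangement calls for it),
#' separated by filler genes, matching what the shipped rule table types as
#' arrangements I-IV:
#' I = no `hyp`, no `crtW`; II = `hyp`; III = `crtW` adjacent to `crtZ`;
#' IV = both.
#'
#' @param arrangement one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param seed integer seed (gene lengths and gaps are randomized).
#' @param max_gap the gap bound the cluster is built to respect.
#' @return `data.frame` of gene features (see [detect_crt_cluster()]).
#' @export
gen_crt_annotation <- function(arrangement = c("I", "II", "III", "IV"),
                               seed = 1, max_gap = 500) {
  known <- c("I", "II", "III", "IV")
  if (!is.character(arrangement) || length(arrangement) != 1 ||
      !arrangement %in% known) {
    stop("unknown arrangement '", paste(arrangement, collapse = ","),
         "'; known labels: ", paste(known, collapse = ", "))
  }
  with_rng(seed, {
    feats <- list()
    pos <- sample(200:800, 1)
    add <- function(name, strand = "+", gap_after = NULL) {
      len <- sample(600:1200, 1)
      feats[[length(feats) + 1L]] <<- data.frame(
        gene_id = sprintf("gene%03d", length(feats) + 1L),
        name = name, contig = "contig1",
        start = pos, end = pos + len - 1L, strand = strand)
      gap <- gap_after %||% sample(20:min(200, max_gap - 1L), 1)
      pos <<- pos + len + gap
    }
    big_gap <- function() pos <<- pos + max_gap + sample(1000:2500, 1)

    add("crtB"); add("log"); add("crtI")
    if (arrangement %in% c("II", "IV")) add("hyp")
    add("crtY")
    big_gap()
    add("filler1", sample(c("+", "-"), 1)); big_gap()
    add("crtE"); big_gap()
    add("filler2", sample(c("+", "-"), 1)); big_gap()
    add("crtG", gap_after = sample(20:80, 1)); add("DUF2141")
    big_gap()
    if (arrangement %in% c("III", "IV")) {
      add("crtW", gap_after = sample(20:80, 1))
    }
    add("crtZ")
    big_gap()
    add("filler3", sample(c("+", "-"), 1))
    do.call(rbind, feats)
  })
}
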