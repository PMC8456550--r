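#' Infer the focal gene's regulator network from evidence matrices
#'
#' A transcription factor qualifies as a level-1 regulator when it has both
#' DNA-binding evidence and expression evidence (activator or inhibitor) on
#' the focal gene; a level-k regulator has both evidence types on at least
#' one level-(k-1) regulator. A TF reachable at several levels is recorded at
#' its minimum level. Edge direction is \code{"activates"} when only the
#' activator matrix supports it, \code{"inhibits"} when only the inhibitor
#' matrix does, and \code{"unknown"} when both do. Self-loops are permitted
#' as edges but never promote a TF across levels.
#'
#' @param focal_gene target gene name (must be a column of the matrices).
#' @param binding,expr_activator,expr_inhibitor logical/0-1 matrices with TFs
#'   as rows and target genes as columns, sharing dimnames.
#' @param max_level deepest level to expand; default 2.
#' @return a list of class \code{"regulator_network"} with \code{focal_gene},
#'   \code{levels} (named integer vector, TF -> minimum level), and
#'   \code{edges} (data frame tf, target, direction).
#' @export
infer_regulators <- function(focal_gene, binding, expr_activator,
                             expr_inhibitor, max_level = 2) {
  binding <- as.matrix(binding) > 0
  act <- as.matrix(expr_activator) > 0
  inh <- as.matrix(expr_inhibitor) > 0
  tfs <- rownames(binding)
  targets <- colnames(binding)
  stopifnot(!is.null(tfs), !is.null(targets))
  if (!focal_gene %in% targets) stop("focal gene absent from target namespace")

  supported <- binding & (act | inh)   # TF x target: both evidence types
  level <- stats::setNames(integer(0), character(0))
  frontier <- focal_gene
  edges <- list()
  for (lev in seq_len(max_level)) {
    new_tfs <- character(0)
    for (tgt in frontier) {
      if (!tgt %in% targets) next
      regs <- tfs[supported[, tgt]]
      regs <- regs[regs != tgt]        # self-loops do not promote levels
      for (tf in regs) {
        dir <- if (act[tf, tgt] && inh[tf, tgt]) "unknown"
               else if (act[tf, tgt]) "activates" else "inhibits"
        edges[[length(edges) + 1L]] <-
          data.frame(tf = tf, target = tgt, direction = dir,
                     stringsAsFactors = FALSE)
        if (!tf %in% names(level)) {
          level[tf] <- lev
          new_tfs <- c(new_tfs, tf)
        }
      }
    }
    frontier <- new_tfs
    if (length(frontier) == 0) break
  }
  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(tf = character(0), target = character(0),
               direction = character(0))
  structure(
    list(focal_gene = focal_gene, levels = level, edges = edges),
    class = "regulator_network"
  )
}

#' @export
print.regulator_network <- function(x, ...) {
  cat(sprintf("Regulator network of %s: %d TFs (%s), %d edges\n",
              x$focal_gene, length(x$levels),
              paste(sprintf("level %d: %d", sort(unique(x$levels)),
                            tabulate(x$levels)[sort(unique(x$levels))]),
                    collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Test enrichment of mutations in the inferred regulator network
#'
#' 2 x 2 G-test of mutation set (trans-regulatory vs non-regulatory) against
#' membership of the mutated gene in the network's regulator set (all
#' levels). Also reports the fold-enrichment, i.e. the ratio of in-network
#' proportions between the two sets.
#'
#' @param trans_set,nonreg_set coding mutation data frames with a \code{gene}
#'   column.
#' @param network a \code{"regulator_network"} from [infer_regulators()], or
#'   a character vector of network gene names.
#' @return list with the \code{table}, \code{g_test}, per-set
#'   \code{proportions} in-network, and \code{fold_enrichment}.
#' @export
network_membership_test <- function(trans_set, nonreg_set, network) {
  genes <- if (inherits(network, "regulator_network")) names(network$levels)
           else as.character(network)
  ti <- trans_set$gene %in% genes
  ni <- nonreg_set$gene %in% genes
  tab <- rbind(trans = c(inside = sum(ti), outside = sum(!ti)),
               nonreg = c(inside = sum(ni), outside = sum(!ni)))
  prop <- c(trans = mean(ti), nonreg = mean(ni))
  list(
    table = tab,
    g_test = g_test_rxc(tab),
    proportions = prop,
    fold_enrichment = unname(prop["trans"] / prop["nonreg"])
  )
}
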