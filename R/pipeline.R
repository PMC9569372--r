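## End-to-end driver: prized interactome -> Steiner forest -> regulatory
## network -> regulator ranking.

#' Run the network-inference pipeline
#'
#' Assigns prizes from the two DE contrasts, solves the Prize-Collecting
#' Steiner Forest, induces the regulatory network on the forest nodes and
#' ranks its transcriptional regulators.
#'
#' @param interactome assembled interactome.
#' @param de_early,de_late DE tables (early prizes the protein layer,
#'   late the RNA layer).
#' @param beta prize scaling.
#' @param omega root-opening cost of the forest formulation.
#' @param fdr_max significance cutoff for prize eligibility and target
#'   classification.
#' @return list of class \code{prizenet_run}: \code{prizes},
#'   \code{instance}, \code{forest}, \code{network}, \code{regulators},
#'   \code{ranking}.
#' @export
run_pipeline <- function(interactome, de_early, de_late,
                         beta = 1.0, omega = 1.0, fdr_max = 0.01) {
  prizes <- suppressMessages(assign_prizes(interactome, de_early, de_late,
                                           beta = beta, fdr_max = fdr_max))
  instance <- prized_instance(interactome, prizes, omega = omega)
  forest <- solve_pcsf(instance)
  network <- induce_network(forest, interactome)
  regulators <- find_regulators(network)
  ranking <- if (length(regulators))
    rank_regulators(regulators, de_early, de_late, network,
                    fdr_max = fdr_max)
  else NULL
  structure(list(prizes = prizes, instance = instance, forest = forest,
                 network = network, regulators = regulators,
                 ranking = ranking),
            class = "prizenet_run")
}

#' @export
print.prizenet_run <- function(x, ...) {
  cat("prizenet pipeline run\n")
  print(x$instance)
  print(x$forest)
  print(x$network)
  cat(sprintf("  %d transcriptional regulators\n", length(x$regulators)))
  if (!is.null(x$ranking)) {
    cat("  top of ranking:\n")
    print.data.frame(utils::head(as.data.frame(x$ranking), 3L))
  }
  invisible(x)
}
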