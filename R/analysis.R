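#' Full topology analysis of a smoothed system
#'
#' Smooths the system (all chains jointly, each seeing the others as
#' obstacles), then classifies every chain: planar projection, DT code
#' under implicit closure, Reidemeister simplification, Alexander-Briggs
#' lookup, subentanglement scan (composite factors), and pairwise link
#' detection.
#'
#' @param system a [bead_chain], list of them, or the result of
#'   [smooth_chains] (reuse of an existing smoothing run).
#' @param cfg a [smooth_config].
#' @return an object of class `topology_result`: per-chain `label`
#'   (Alexander-Briggs, composites joined with `#`), `dt` (simplified DT
#'   values), `subentanglements`; `links` (data frame); `converged`.
#' @export
#' @examples
#' \donttest{
#' res <- analyze_topology(make_chain("stick_trefoil"))
#' res$chains[[1]]$label  # "3_1"
#' }
analyze_topology <- function(system, cfg = smooth_config()) {
  if (is.list(system) && !is.null(system$trajectory)) {
    run <- system
  } else {
    run <- smooth_chains(as_system(system), cfg)
  }
  chains <- lapply(run$system, function(ch) {
    n <- nrow(ch$beads)
    if (n <= 2L) {
      return(list(chain_id = ch$chain_id, label = "0_1",
                  dt = integer(0),
                  subentanglements = list(ranges = list(),
                                          labels = character(0),
                                          label = "0_1")))
    }
    rot <- choose_projection(ch)
    code <- simplify_diagram(build_diagram(ch, rot))
    label <- classify_knot(code)
    sub <- find_subentanglements(ch, cfg)
    if (length(sub$labels) >= 2L) label <- sub$label
    list(chain_id = ch$chain_id, label = label, dt = code$values,
         subentanglements = sub)
  })
  links <- detect_links(run$system)
  structure(list(chains = chains, links = links,
                 system = run$system, trajectory = run$trajectory,
                 converged = run$converged),
            class = "topology_result")
}

#' @export
print.topology_result <- function(x, ...) {
  for (ch in x$chains) {
    cat(sprintf("chain %s: %s ; DT: %s\n", ch$chain_id, ch$label,
                if (length(ch$dt)) paste(ch$dt, collapse = " ") else "(empty)"))
  }
  if (nrow(x$links)) {
    for (i in seq_len(nrow(x$links))) {
      cat(sprintf("link %s-%s: %s (%d crossings)\n",
                  x$links$chain_a[i], x$links$chain_b[i],
                  if (x$links$linked[i]) "linked" else "unlinked",
                  x$links$crossings[i]))
    }
  }
  if (!x$converged) cat("warning: smoothing unconverged\n")
  invisible(x)
}

# machine-readable form
topology_as_list <- function(x) {
  list(
    chains = lapply(x$chains, function(ch) list(
      chain = ch$chain_id, label = ch$label, dt = ch$dt,
      subentanglements = lapply(seq_along(ch$subentanglements$labels),
        function(i) list(range = ch$subentanglements$ranges[[i]],
                         label = ch$subentanglements$labels[[i]])))),
    links = if (nrow(x$links)) x$links else NULL,
    converged = x$converged
  )
}
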