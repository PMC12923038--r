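#' Specification for a synthetic fixture
#'
#' Describes a complete, statistically controlled toy dataset: a rooted
#' ontology with leaf gene annotations and disease-to-term mappings, an
#' enhancer catalog organized in modules (block model) with target-gene
#' sets and sequences derived from per-module ancestor sequences, and
#' planted disease-enhancer associations.  The signal `regime` controls
#' which layers carry recoverable structure:
#' \describe{
#'   \item{`"A"`}{both layers informative: gene sets and sequences are
#'     module-structured and associations are planted within modules}
#'   \item{`"B"`}{gene layer only: sequence assignment is shuffled}
#'   \item{`"C"`}{sequence layer only: target-set assignment is shuffled}
#'   \item{`"null"`}{associations are uniform over enhancers}
#' }
#'
#' @param n_terms number of ontology terms (>= 3).
#' @param branching branching factor of the term tree.
#' @param genes_per_term distinct genes annotated to each leaf term.
#' @param n_enhancers number of enhancers.
#' @param n_modules number of enhancer modules.
#' @param module_gene_pool genes in each module's (disjoint) pool.
#' @param p_in probability that an enhancer carries each gene of its own
#'   module pool.
#' @param p_out probability that it carries each gene of another pool.
#' @param base_seq_length sequence length of the first module's ancestor.
#' @param seq_length_step length increment per module (module-specific
#'   lengths keep cross-module percent identity low).
#' @param mutation_rate per-base substitution rate from the module
#'   ancestor sequence.
#' @param n_diseases number of diseases.
#' @param assoc_per_disease planted associations per disease (>= 3 so
#'   that 3-fold cross-validation eligibility holds).
#' @param regime signal regime, see above.
#' @param seed master RNG seed; identical specs give identical fixtures.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_terms = 25L, branching = 2L, genes_per_term = 4L,
                         n_enhancers = 60L, n_modules = 6L,
                         module_gene_pool = 20L, p_in = 0.7, p_out = 0.03,
                         base_seq_length = 80L, seq_length_step = 60L,
                         mutation_rate = 0.05, n_diseases = 8L,
                         assoc_per_disease = 5L,
                         regime = c("A", "B", "C", "null"), seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(n_terms >= 3L, branching >= 1L, n_enhancers >= n_modules,
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            assoc_per_disease >= 3L,
            assoc_per_disease <= n_enhancers %/% n_modules)
  if (regime %in% c("A", "B", "C") && p_in <= p_out)
    stop("informative regimes need p_in > p_out")
  structure(as.list(environment()), class = "fixture_spec")
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat(sprintf(paste0("<fixture_spec regime=%s seed=%s> %d terms, %d ",
                     "enhancers in %d modules, %d diseases\n"),
              x$regime, format(x$seed), x$n_terms, x$n_enhancers,
              x$n_modules, x$n_diseases))
  invisible(x)
}

#' Generate the synthetic ontology, annotations and disease map
#'
#' Terms form a `branching`-ary tree; every leaf is annotated with
#' `genes_per_term` distinct genes, so IC is finite for all terms and
#' deeper terms are at least as informative as their ancestors.
#' Diseases are mapped to leaves, with diseases of the same module
#' placed on neighbouring leaves so that within-module disease pairs are
#' semantically closer.
#'
#' @param spec a [fixture_spec()].
#' @return list with `dag` (annotated), `annotations`, `disease_map`.
#' @export
generate_ontology <- function(spec) {
  nt <- spec$n_terms
  terms <- sprintf("T%02d", seq_len(nt))
  parents <- lapply(seq_len(nt), function(i)
    if (i == 1L) character(0) else terms[(i - 2L) %/% spec$branching + 1L])
  names(parents) <- terms
  dag <- ontology_dag(terms, parents)
  leaves <- terms[vapply(dag$children[terms], length, 1L) == 0L]

  annotations <- withr::with_seed(derive_seed(spec$seed, "ontology"), {
    g <- 0L
    do.call(rbind, lapply(leaves, function(t) {
      genes <- sprintf("OG%03d", g + seq_len(spec$genes_per_term))
      g <<- g + spec$genes_per_term
      data.frame(term = t, gene = genes, stringsAsFactors = FALSE)
    }))
  })

  # diseases of the same module sit on neighbouring leaves
  module_of_disease <- ((seq_len(spec$n_diseases) - 1L) %% spec$n_modules) + 1L
  leaf_group <- sort(rep_len(seq_len(spec$n_modules), length(leaves)))
  disease_map <- do.call(rbind, lapply(seq_len(spec$n_diseases), function(d) {
    mod <- module_of_disease[d]
    pool <- leaves[leaf_group == mod]
    nth <- sum(module_of_disease[seq_len(d)] == mod)
    data.frame(disease = sprintf("D%02d", d),
               term = pool[((nth - 1L) %% length(pool)) + 1L],
               stringsAsFactors = FALSE)
  }))
  list(dag = annotate_dag(dag, annotations), annotations = annotations,
       disease_map = disease_map)
}

#' Generate the synthetic enhancer catalog and sequences
#'
#' Enhancers are split into contiguous modules.  Each module owns a
#' disjoint gene pool; an enhancer carries each own-pool gene with
#' probability `p_in` and each foreign-pool gene with probability
#' `p_out`.  Sequences are derived from a random module ancestor (one
#' per module, of module-specific length) by per-base substitution at
#' `mutation_rate`.  Regime `"B"` shuffles the enhancer-to-sequence
#' assignment; regime `"C"` shuffles the enhancer-to-target-set
#' assignment.
#'
#' @param spec a [fixture_spec()].
#' @return list with `catalog` (an [enhancer_catalog()]), `sequences`
#'   (named character vector), `modules` (named module index).
#' @export
generate_enhancer_catalog <- function(spec) {
  ne <- spec$n_enhancers
  ids <- sprintf("E%02d", seq_len(ne))
  modules <- sort(rep_len(seq_len(spec$n_modules), ne))
  names(modules) <- ids
  pools <- lapply(seq_len(spec$n_modules), function(m)
    sprintf("G%03d", (m - 1L) * spec$module_gene_pool +
              seq_len(spec$module_gene_pool)))
  universe <- unlist(pools)

  out <- withr::with_seed(derive_seed(spec$seed, "catalog"), {
    targets <- lapply(seq_len(ne), function(i) {
      m <- modules[i]
      own <- pools[[m]][stats::runif(length(pools[[m]])) < spec$p_in]
      other <- unlist(pools[-m])
      other <- other[stats::runif(length(other)) < spec$p_out]
      g <- c(own, other)
      if (!length(g)) g <- sample(pools[[m]], 1L)
      sort(g)
    })
    names(targets) <- ids

    lens <- spec$base_seq_length +
      (seq_len(spec$n_modules) - 1L) * spec$seq_length_step
    bases <- c("A", "C", "G", "T")
    ancestors <- lapply(lens, function(L)
      sample(bases, L, replace = TRUE))
    sequences <- vapply(seq_len(ne), function(i) {
      s <- ancestors[[modules[i]]]
      mut <- stats::runif(length(s)) < spec$mutation_rate
      if (any(mut))
        s[mut] <- vapply(s[mut], function(b)
          sample(setdiff(bases, b), 1L), "")
      paste(s, collapse = "")
    }, "")
    names(sequences) <- ids

    if (spec$regime == "B")
      sequences <- stats::setNames(sequences[sample(ne)], ids)
    if (spec$regime == "C")
      targets <- stats::setNames(targets[sample(ne)], ids)
    list(targets = targets, sequences = sequences)
  })

  widths <- nchar(out$sequences)
  intervals <- genomic_intervals(chrom = "chr1",
                                 start = (seq_len(ne) - 1L) * 2000L,
                                 end = (seq_len(ne) - 1L) * 2000L + widths,
                                 id = ids)
  list(catalog = enhancer_catalog(out$targets, intervals = intervals,
                                  gene_universe = universe),
       sequences = out$sequences, modules = modules)
}

#' Plant disease-enhancer associations
#'
#' In the signal regimes each disease's enhancers are drawn uniformly
#' without replacement from its module; in the null regime from all
#' enhancers.  Every disease receives `assoc_per_disease` associations,
#' so all diseases are eligible for 3-fold cross-validation.
#'
#' @param spec a [fixture_spec()].
#' @param modules named module assignment from
#'   [generate_enhancer_catalog()].
#' @return association data.frame (`disease`, `enhancer`).
#' @export
plant_associations <- function(spec, modules) {
  ids <- names(modules)
  withr::with_seed(derive_seed(spec$seed, "associations"), {
    do.call(rbind, lapply(seq_len(spec$n_diseases), function(d) {
      pool <- if (spec$regime == "null") ids
        else ids[modules == ((d - 1L) %% spec$n_modules) + 1L]
      data.frame(disease = sprintf("D%02d", d),
                 enhancer = sort(sample(pool, spec$assoc_per_disease)),
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Generate a complete synthetic fixture
#'
#' Runs the ontology, catalog and association generators, scores all
#' pairwise sequence similarities with the surrogate aligner, and
#' returns everything needed to build the networks and run the pipeline
#' end-to-end.  Identical specs (including the seed) give identical
#' fixtures.
#'
#' @param spec a [fixture_spec()].
#' @return list of class `fixture`: `spec`, `dag`, `annotations`,
#'   `disease_map`, `catalog`, `sequences`, `modules`, `simmat`,
#'   `associations`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  ont <- generate_ontology(spec)
  cat_ <- generate_enhancer_catalog(spec)
  assoc <- plant_associations(spec, cat_$modules)
  simmat <- sequence_similarity_matrix(cat_$sequences)
  structure(list(spec = spec, dag = ont$dag, annotations = ont$annotations,
                 disease_map = ont$disease_map, catalog = cat_$catalog,
                 sequences = cat_$sequences, modules = cat_$modules,
                 simmat = simmat, associations = assoc),
            class = "fixture")
}

#' @export
print.fixture <- function(x, ...) {
  print(x$spec)
  invisible(x)
}

#' Build the three networks from a fixture
#'
#' @param fix a [generate_fixture()] result.
#' @param alpha gEnhNet significance cutoff (default 0.05).
#' @return list with `gene_net`, `seq_net`, `disease_net`.
#' @export
fixture_networks <- function(fix, alpha = 0.05) {
  list(gene_net = build_shared_gene_network(fix$catalog, alpha = alpha),
       seq_net = build_sequence_network(fix$simmat),
       disease_net = build_disease_network(fix$dag, fix$disease_map))
}

#' Write a fixture to disk in the pipeline's input dialects
#'
#' Emits `ontology.obo`, `annotations.tsv`, `disease_map.tsv`,
#' `enhancer_genes.tsv`, `enhancers.bed`, `sequences.fasta`,
#' `similarity.tsv` (labelled square dialect) and `associations.tsv`
#' — exactly the formats the package readers consume.
#'
#' @param fix a [generate_fixture()] result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_obo(fix$dag, fp("ontology.obo"))
  write_annotation_table(fix$annotations, fp("annotations.tsv"))
  write_disease_map(fix$disease_map, fp("disease_map.tsv"))
  write_enhancer_catalog(fix$catalog, fp("enhancer_genes.tsv"))
  write_bed(fix$catalog$intervals, fp("enhancers.bed"))
  write_fasta(fix$sequences, fp("sequences.fasta"))
  write_similarity_matrix(fix$simmat, fp("similarity.tsv"),
                          dialect = "square")
  write_association_table(fix$associations, fp("associations.tsv"))
  invisible(dir)
}

#' Read a fixture directory back into memory
#'
#' Inverse of [write_fixture()]; used by the command-line interface.
#'
#' @param dir directory written by [write_fixture()].
#' @return list with `dag`, `disease_map`, `catalog`, `simmat`,
#'   `associations`.
#' @export
read_fixture <- function(dir) {
  fp <- function(x) file.path(dir, x)
  dag <- read_obo(fp("ontology.obo"))
  dag <- annotate_dag(dag, read_annotation_table(fp("annotations.tsv")))
  list(dag = dag,
       disease_map = read_disease_map(fp("disease_map.tsv")),
       catalog = read_enhancer_catalog(
         fp("enhancer_genes.tsv"),
         bed = if (file.exists(fp("enhancers.bed"))) fp("enhancers.bed")),
       simmat = read_similarity_matrix(fp("similarity.tsv"),
                                       dialect = "square"),
       associations = read_association_table(fp("associations.tsv")))
}
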