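# End-to-end orchestration. Output artifacts are numbered by pipeline
# step; all tables report the user's original identifiers (via the
# reversible mapping from step 0), while Newick files keep the sanitized
# ids for tree-format safety.

#' Assemble a pipeline configuration
#'
#' Collects all paths, tool choices and thresholds for [runPipeline()].
#' Values can equally come from a `key = value` config file
#' ([readPipelineConfig()]); arguments override file values.
#'
#' @param subject FASTA of peptide or coding sequences to annotate.
#' @param outDir output directory (created; must be writable).
#' @param baits,outgroup bait / outgroup FASTA paths.
#' @param referenceTable optional annotation TSV ([readReferenceTable()]).
#' @param domainHmm optional family profile HMM (required for
#'   `search = "hmmer"` and for the domain/binding step).
#' @param motifDir optional directory of subfamily motif HMMs.
#' @param landmarks optional FASTA of landmark sequences for the step-7/9
#'   trees (defaults to the bait collection).
#' @param search `"blast"` or `"hmmer"`.
#' @param aligner `"mafft"` or `"muscle"`.
#' @param treeTool `"fasttree"`, `"nj"` or `"raxml"`.
#' @param thresholds a [searchThresholds()] list.
#' @param classify a [classifyParams()] object (`requireDomain` lives
#'   here).
#' @param collapse run the paralog-collapsing steps 8-9?
#' @param cutoffFactor collapse distance cutoff factor (default 1).
#' @param referenceId bait id anchoring the binding-position mapping.
#' @param basicRegionSpan,minBasic see [predictBinding()].
#' @param subjectType passed to [readProteins()].
#' @param seed integer seed forwarded to stochastic external tools.
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(subject, outDir, baits, outgroup,
                           referenceTable = NULL, domainHmm = NULL,
                           motifDir = NULL, landmarks = NULL,
                           search = c("blast", "hmmer"),
                           aligner = c("mafft", "muscle"),
                           treeTool = c("fasttree", "nj", "raxml"),
                           thresholds = searchThresholds(),
                           classify = classifyParams(),
                           collapse = FALSE, cutoffFactor = 1,
                           referenceId = NULL, basicRegionSpan = 1:16,
                           minBasic = 5,
                           subjectType = "auto", seed = 1L) {
  cfg <- list(subject = subject, outDir = outDir, baits = baits,
              outgroup = outgroup, referenceTable = referenceTable,
              domainHmm = domainHmm, motifDir = motifDir,
              landmarks = landmarks, search = match.arg(search),
              aligner = match.arg(aligner), treeTool = match.arg(treeTool),
              thresholds = thresholds, classify = classify,
              collapse = isTRUE(collapse), cutoffFactor = cutoffFactor,
              referenceId = referenceId, basicRegionSpan = basicRegionSpan,
              minBasic = minBasic, subjectType = subjectType,
              seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a `key = value` config file
#'
#' Lines of the form `key = value` (`#` comments allowed); keys mirror the
#' [pipelineConfig()] arguments, with numeric threshold keys
#' `min_bit_score`, `min_similarity`, `min_align_length`, `n_neighbours`,
#' `min_score`, `outlier_factor`, `min_baits`, `parallel_threshold`,
#' `bin_size`, `cutoff_factor`, `min_basic` and logical keys `collapse`,
#' `require_domain`.
#'
#' @param path config file.
#' @param ... overrides forwarded to [pipelineConfig()] (flags beat file
#'   values).
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  num <- function(k, d) if (k %in% names(vals)) as.numeric(vals[[k]]) else d
  chr <- function(k, d = NULL) if (k %in% names(vals)) vals[[k]] else d
  lgl <- function(k, d) if (k %in% names(vals))
    tolower(vals[[k]]) %in% c("true", "yes", "1") else d
  base <- list(
    subject = chr("subject"), outDir = chr("out_dir"),
    baits = chr("baits"), outgroup = chr("outgroup"),
    referenceTable = chr("reference_table"), domainHmm = chr("domain_hmm"),
    motifDir = chr("motif_dir"), landmarks = chr("landmarks"),
    search = chr("search", "blast"), aligner = chr("aligner", "mafft"),
    treeTool = chr("tree", "fasttree"),
    thresholds = searchThresholds(num("min_bit_score", 60),
                                  num("min_similarity", 40),
                                  num("min_align_length", 80)),
    classify = classifyParams(num("n_neighbours", 3),
                              num("min_score", 0.5),
                              num("outlier_factor", 5),
                              num("min_baits", 1),
                              lgl("require_domain", FALSE),
                              num("parallel_threshold", 600),
                              num("bin_size", 500)),
    collapse = lgl("collapse", FALSE),
    cutoffFactor = num("cutoff_factor", 1),
    referenceId = chr("reference_id"),
    minBasic = num("min_basic", 5),
    seed = num("seed", 1))
  over <- list(...)
  base[names(over)] <- over
  do.call(pipelineConfig, base)
}

.tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full annotation pipeline
#'
#' Executes: input validation and identifier cleaning (step 0), candidate
#' search (1), two-pass ingroup/outgroup classification (2), final tree
#' with the full bait collection (3), ortholog assignment and annotation
#' transfer (4), domain check and binding-group prediction (5), subfamily
#' motif scan (6), landmark tree (7), and — only when `collapse` is set —
#' paralog collapsing with representative and subfamily trees (8-9).
#' Tables carry the original input identifiers. A manifest (JSON) records
#' parameters, input checksums and every output file.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()] /
#'   [readPipelineConfig()].
#' @return invisibly, a list with the main in-memory results
#'   (`initialCandidates`, `finalCandidates`, `classification`,
#'   `finalTree`, `orthologs`, `annotation`, `domains`, `binding`,
#'   `motifs`, `groups`, `subfamilies`, `idMap`, `manifest`).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  config <- validateInputs(config)
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = .manifestParams(config),
                   inputs = .inputChecksums(config), outputs = list())
  outputs <- character()
  addOut <- function(p) { outputs <<- c(outputs, p); p }
  res <- list()

  ## step 0: read, sanitize, map
  subject <- readProteins(config$subject, type = config$subjectType)
  san <- sanitizeIdentifiers(subject)
  subject <- san$seqs
  res$idMap <- san$map
  baits <- config$parsed$baits
  outgroup <- config$parsed$outgroup
  clash <- intersect(names(subject), c(names(baits), names(outgroup)))
  if (length(clash))
    stop("subject identifiers collide with bait/outgroup ids: ",
         paste(clash, collapse = ", "))
  writeFastaFile(subject, addOut(file.path(outDir, "00_cleaned_subject.fasta")))
  writeIdentifierMap(san$map, addOut(file.path(outDir, "00_id_mapping.tsv")))
  orig <- function(ids) restoreIdentifiers(ids, san$map)

  ## step 1: candidate search
  if (config$search == "blast") {
    cand <- blastCandidates(subject, baits, config$thresholds,
      rawFile = addOut(file.path(outDir, "01_blast_raw.tsv")),
      filteredFile = addOut(file.path(outDir, "01_blast_filtered.tsv")))
  } else {
    if (is.null(config$domainHmm))
      stop("search = 'hmmer' needs a domain HMM")
    cand <- hmmerCandidates(subject, config$domainHmm)
  }
  res$initialCandidates <- cand
  writeLines(orig(cand), addOut(file.path(outDir, "01_initial_candidates.txt")))
  if (!length(cand)) {
    warning("no initial candidates; pipeline stops after step 1")
    res$finalCandidates <- character()
    res$manifest <- .writeManifest(manifest, outputs, outDir)
    return(invisible(res))
  }
  writeFastaFile(subject[cand],
                 addOut(file.path(outDir, "01_initial_candidates.fasta")))

  ## step 2: two-pass classification
  cls <- twoPassClassify(subject[cand], baits, outgroup,
                         params = config$classify,
                         domainHmm = config$domainHmm,
                         alignTool = config$aligner,
                         treeTool = config$treeTool, seed = config$seed)
  res$classification <- cls
  .writePassOutputs(cls$pass1, "02_pass1", outDir, orig, addOut)
  if (!is.null(cls$pass2))
    .writePassOutputs(cls$pass2, "02_pass2", outDir, orig, addOut)
  final <- cls$final
  res$finalCandidates <- final
  writeLines(orig(final), addOut(file.path(outDir, "02_final_candidates.txt")))
  if (!length(final)) {
    warning("no final candidates after classification")
    res$manifest <- .writeManifest(manifest, outputs, outDir)
    return(invisible(res))
  }
  writeFastaFile(subject[final],
                 addOut(file.path(outDir, "02_final_candidates.fasta")))

  ## step 3: final tree (final candidates + complete bait collection)
  finalSet <- c(subject[final], baits)
  aln <- alignSequences(finalSet, tool = config$aligner)
  trim <- trimAlignment(aln)
  writeFastaFile(trim$alignment,
                 addOut(file.path(outDir, "03_trimmed_alignment.fasta")))
  tr <- buildTree(trim$alignment, tool = config$treeTool,
                  newickFile = addOut(file.path(outDir, "03_final_tree.nwk")),
                  seed = config$seed)
  finalTree <- labeledTree(tr, c(
    setNames(rep("candidate", length(final)), final),
    setNames(rep("ingroup_bait", length(baits)), names(baits))))
  res$finalTree <- finalTree

  ## step 4: orthologs + annotation
  orth <- assignOrthologs(finalTree)
  ann <- annotateCandidates(orth, config$parsed$reference)
  res$orthologs <- orth
  res$annotation <- ann
  outOrth <- ann
  outOrth$candidate <- orig(outOrth$candidate)
  .tsv(outOrth, addOut(file.path(outDir, "04_orthologs.tsv")))
  byBait <- attr(orth, "byBait")
  .tsv(data.frame(bait = names(byBait),
                  candidates = vapply(byBait, function(v)
                    paste(orig(v), collapse = ","), character(1))),
       addOut(file.path(outDir, "04_bait_to_candidates.tsv")))

  ## step 5: domain check + binding prediction
  if (!is.null(config$domainHmm)) {
    dom <- detectDomains(subject[final], config$domainHmm,
      fastaFile = addOut(file.path(outDir, "05_domains.fasta")))
    res$domains <- dom
    outDom <- dom
    outDom$candidate <- orig(outDom$candidate)
    .tsv(outDom, addOut(file.path(outDir, "05_domain_check.tsv")))
    refId <- config$referenceId
    if (!is.null(refId) && refId %in% names(baits)) {
      refDom <- detectDomains(baits[refId], config$domainHmm)
      if (refDom$present[1]) {
        cols <- mapReferenceColumns(aln, refId, refDom$env_start[1],
                                    refDom$env_end[1], trimReport = trim)
        bind <- predictBinding(trim$alignment, cols, final,
                               basicRegionSpan = config$basicRegionSpan,
                               minBasic = config$minBasic)
        res$binding <- bind
        outBind <- bind
        outBind$candidate <- orig(outBind$candidate)
        .tsv(outBind, addOut(file.path(outDir, "05_binding_groups.tsv")))
      } else {
        warning("no domain detected in reference ", refId,
                "; binding prediction skipped")
      }
    }
  }

  ## step 6: motif scan
  if (!is.null(config$motifDir)) {
    motifs <- scanMotifs(subject[final], config$motifDir,
      fastaFile = file.path(outDir, "06_motifs.fasta"))
    res$motifs <- motifs
    outMot <- motifs
    outMot$candidate <- orig(outMot$candidate)
    .tsv(outMot, addOut(file.path(outDir, "06_motifs.tsv")))
  }

  ## step 7: landmark tree
  landmarks <- if (!is.null(config$landmarks)) readProteins(config$landmarks)
               else baits
  lmTree <- representativeTree(subject[final], landmarks,
                               alignTool = config$aligner,
                               treeTool = config$treeTool,
                               seed = config$seed, anchorRole = "reference")
  ape::write.tree(treePhylo(lmTree),
                  addOut(file.path(outDir, "07_landmark_tree.nwk")))
  res$landmarkTree <- lmTree

  ## steps 8-9: paralog collapsing (optional)
  if (config$collapse) {
    groups <- collapseParalogs(finalTree, subject[final],
                               cutoffFactor = config$cutoffFactor)
    res$groups <- groups
    outGroups <- groups
    for (cl in c("seed", "representative"))
      outGroups[[cl]] <- orig(outGroups[[cl]])
    outGroups$members <- vapply(strsplit(groups$members, ","), function(v)
      paste(orig(v), collapse = ","), character(1))
    .tsv(outGroups, addOut(file.path(outDir, "08_paralog_groups.tsv")))
    reps <- subject[groups$representative]
    writeFastaFile(reps, addOut(file.path(outDir, "08_representatives.fasta")))
    repTree <- representativeTree(reps, baits, alignTool = config$aligner,
                                  treeTool = config$treeTool,
                                  seed = config$seed)
    ape::write.tree(treePhylo(repTree),
                    addOut(file.path(outDir, "08_representative_tree.nwk")))
    lmRepTree <- representativeTree(reps, landmarks,
                                    alignTool = config$aligner,
                                    treeTool = config$treeTool,
                                    seed = config$seed,
                                    anchorRole = "reference")
    if (!is.null(config$parsed$reference)) {
      subf <- assignSubfamily(lmRepTree, names(reps),
                              config$parsed$reference)
      res$subfamilies <- subf
      outSubf <- subf
      outSubf$representative <- orig(outSubf$representative)
      .tsv(outSubf, addOut(file.path(outDir, "09_subfamilies.tsv")))
      decorated <- representativeTree(reps, landmarks,
                                      referenceTable = config$parsed$reference,
                                      alignTool = config$aligner,
                                      treeTool = config$treeTool,
                                      seed = config$seed,
                                      anchorRole = "reference")
      ape::write.tree(treePhylo(decorated),
                      addOut(file.path(outDir,
                                       "09_landmark_representative_tree.nwk")))
    } else {
      ape::write.tree(treePhylo(lmRepTree),
                      addOut(file.path(outDir,
                                       "09_landmark_representative_tree.nwk")))
    }
  }

  res$manifest <- .writeManifest(manifest, outputs, outDir)
  invisible(res)
}

.writePassOutputs <- function(pass, prefix, outDir, orig, addOut) {
  tab <- pass$results
  tab$candidate <- orig(tab$candidate)
  .tsv(tab, addOut(file.path(outDir, paste0(prefix, "_classification.tsv"))))
  for (b in seq_along(pass$trees)) {
    ape::write.tree(treePhylo(pass$trees[[b]]),
                    addOut(file.path(outDir,
                                     sprintf("%s_bin%d.nwk", prefix, b))))
  }
}

.manifestParams <- function(config) {
  cl <- config$classify
  list(search = config$search, aligner = config$aligner,
       tree = config$treeTool,
       min_bit_score = config$thresholds$minBitScore,
       min_similarity = config$thresholds$minSimilarity,
       min_align_length = config$thresholds$minAlignLength,
       n_neighbours = cl@nNeighbours, min_score = cl@minScore,
       outlier_factor = cl@outlierFactor,
       min_baits_in_selection = cl@minBaitsInSelection,
       require_domain = cl@requireDomain,
       parallel_threshold = cl@parallelThreshold, bin_size = cl@binSize,
       collapse = config$collapse, cutoff_factor = config$cutoffFactor,
       reference_id = config$referenceId, min_basic = config$minBasic,
       seed = config$seed)
}

.inputChecksums <- function(config) {
  files <- Filter(function(p) is.character(p) && length(p) == 1 &&
                    file.exists(p),
                  config[c("subject", "baits", "outgroup", "referenceTable",
                           "domainHmm", "landmarks")])
  lapply(files, function(p) unname(tools::md5sum(p)))
}

.writeManifest <- function(manifest, outputs, outDir) {
  manifest$outputs <- basename(outputs)
  missing <- outputs[!file.exists(outputs)]
  if (length(missing))
    warning("manifest lists outputs that were not written: ",
            paste(missing, collapse = ", "))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}
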