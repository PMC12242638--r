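test_that("activity tables parse with rejects reported, never dropped", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("compound_id,smiles,standard_type,standard_value,pchembl_value",
               "a,c1ccncc1,Ki,50,7.3",
               "b,CCO,Kd,8000,5.1",
               "c,CCN,IC50,10,8"), csv)
  p <- parse_activity_table(csv)
  expect_equal(nrow(p$records), 3)
  expect_equal(nrow(p$rejects), 0)

  writeLines(c("compound_id,smiles,standard_type,standard_value",
               "a,c1ccncc1,Ki,50",
               "b,CCO,Kd,N/A",
               "c,not_a_smiles((,Ki,10"), csv)
  p <- parse_activity_table(csv)
  expect_equal(nrow(p$records), 1)
  expect_equal(nrow(p$rejects), 2)
  expect_match(p$rejects$reason[p$rejects$smiles == "CCO"], "non-numeric value")
  expect_match(p$rejects$reason[2], "unparseable SMILES")

  writeLines("compound_id,smiles,standard_type,standard_value", csv)
  p <- parse_activity_table(csv)
  expect_equal(nrow(p$records), 0)

  writeLines(c("id,structure,type", "a,CC,Ki"), csv)
  expect_error(parse_activity_table(csv), "mandatory column")
  expect_error(parse_activity_table(tempfile()), "not found")
})

test_that("activity classification follows the Ki/Kd thresholds", {
  rec <- data.frame(
    compound_id = c("a", "b", "c", "d", "e"),
    smiles = "CC",
    standard_type = c("Ki", "IC50", "Kd", "Kd", "Ki"),
    standard_value = c(50, 10, 2000, 5000, 100),
    pchembl_value = NA, target_id = NA,
    stringsAsFactors = FALSE
  )
  ls <- classify_activity(rec)
  expect_s3_class(ls, "labeled_set")
  expect_setequal(ls$actives$compound_id, c("a", "e"))     # <= 100 nM inclusive
  expect_equal(ls$inactives$compound_id, "d")              # >= 5000 nM inclusive
  expect_equal(ls$excluded$reason[ls$excluded$compound_id == "b"],
               "unsupported type")
  expect_equal(ls$excluded$reason[ls$excluded$compound_id == "c"],
               "intermediate activity")
  # strict boundary flag pushes the 5000 nM record into the intermediate band
  ls2 <- classify_activity(rec, inactive_strict = TRUE)
  expect_equal(nrow(ls2$inactives), 0)
  # negative values are a validation error
  rec$standard_value[1] <- -1
  expect_error(classify_activity(rec), "negative")
})

test_that("classification is a partition and threshold-monotone", {
  for (seed in 1:5) {
    syn <- make_activity_table(8, 12, 4, 3, seed = seed)
    ls <- classify_activity(syn$table)
    expect_equal(nrow(ls$actives) + nrow(ls$inactives) + nrow(ls$excluded),
                 nrow(syn$table))
    expect_length(intersect(ls$actives$compound_id, ls$inactives$compound_id), 0)
    # lowering the active threshold never grows the active set
    ls_lo <- classify_activity(syn$table, active_nM = 10)
    expect_true(all(ls_lo$actives$compound_id %in% ls$actives$compound_id))
  }
})

test_that("duplicate Ki/Kd measurements resolve to the most potent record", {
  rec <- data.frame(
    compound_id = c("a", "a", "a"),
    smiles = "CC",
    standard_type = c("Ki", "Kd", "Ki"),
    standard_value = c(9000, 40, 300),
    pchembl_value = NA, target_id = NA, stringsAsFactors = FALSE
  )
  ls <- classify_activity(rec)
  expect_equal(ls$actives$compound_id, "a")
  expect_equal(ls$actives$standard_value, 40)
  expect_equal(sum(ls$excluded$reason == "duplicate measurement (less potent)"), 2)
})

test_that("structural filters desalt, deduplicate and apply the inclusive MW cutoff", {
  cmp <- data.frame(
    compound_id = c("asp_salt", "asp", "pyridine", "stereo", "big"),
    smiles = c("CC(=O)Oc1ccccc1C(=O)O.[Na+]",
               "OC(=O)c1ccccc1OC(C)=O",       # same molecule, other spelling
               "c1ccncc1",
               "NC(C)C(=O)O",                 # unspecified alanine centre
               paste0("C", strrep("(F)(F)C", 20))),  # heavy fluorocarbon
    stringsAsFactors = FALSE
  )
  out <- apply_structural_filters(cmp)
  expect_equal(out$kept$compound_id, c("asp_salt", "pyridine"))
  expect_false(grepl("Na", out$kept$canonical_smiles[1]))
  expect_setequal(out$removed$reason,
                  c("duplicate structure", "unspecified stereocenter",
                    "MW >= 550"))
  # MW exactly at the cutoff is removed (inclusive rule)
  mw <- out$kept$mol_weight[1]
  at_cut <- apply_structural_filters(out$kept, max_mw = mw)
  expect_true("asp_salt" %in% at_cut$removed$compound_id)
  # idempotence
  again <- apply_structural_filters(out$kept)
  expect_equal(again$kept$canonical_smiles, out$kept$canonical_smiles)
  expect_equal(nrow(again$removed), 0)
})

test_that("specified stereocentres are not flagged as unspecified", {
  expect_equal(count_unspecified_stereocenters("N[C@@H](C)C(=O)O"), 0)
  expect_equal(count_unspecified_stereocenters("NC(C)C(=O)O"), 1)
  expect_equal(count_unspecified_stereocenters("OC1CCCCC1"), 0)  # symmetric
  expect_equal(count_unspecified_stereocenters("CCO"), 0)
})

test_that("hinge-binder filter demands an aromatic N-heterocycle of the right size", {
  expect_true(hinge_motif_filter("c1ccncc1"))            # pyridine
  expect_true(hinge_motif_filter("c1cc[nH]c1"))          # pyrrole (5-ring N)
  expect_true(hinge_motif_filter("c1ccc2ncccc2c1"))      # quinoline
  expect_false(hinge_motif_filter("NC1CCCCC1"))          # no aromatic ring
  expect_false(hinge_motif_filter("c1ccc2ccccc2c1"))     # naphthalene, no N
  expect_false(hinge_motif_filter("c1ccccc1"))
  # a known hinge binder: ruxolitinib's pyrrolopyrimidine
  expect_true(hinge_motif_filter(
    "C1CCC(C1)C(CC#N)n1cc(cn1)-c1ncnc2[nH]ccc12"))
})

test_that("diversity selection cuts the Tanimoto tree and returns medoids", {
  cmp <- data.frame(
    compound_id = c("p1", "p2", "hex"),
    smiles = c("c1ccncc1", "C1=CC=NC=C1", "CCCCCC"),
    stringsAsFactors = FALSE
  )
  out <- diversity_select(cmp)
  expect_equal(out$n_clusters, 2)  # two pyridine spellings collapse
  expect_equal(out$cluster_labels[1], out$cluster_labels[2])
  # threshold >= 1 merges everything; threshold 0 splits by unique structure
  expect_equal(diversity_select(cmp, distance_threshold = 1)$n_clusters, 1)
  expect_equal(diversity_select(cmp, distance_threshold = 0)$n_clusters, 2)
  expect_error(diversity_select(cmp[0, ]), "no compounds")
})
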