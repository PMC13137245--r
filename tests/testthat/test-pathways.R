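test_that("pathway enumeration matches the brute-force oracle for up to 3 shifts", {
  cases <- list(
    list(glycan = "Glcb", carbonyl = 1, blocked = integer(0)),
    list(glycan = "Fru", carbonyl = 2, blocked = integer(0)),
    list(glycan = "Manb1-2Manb", carbonyl = 1, blocked = 2L),
    list(glycan = "Manb1-3Manb", carbonyl = 1, blocked = 3L),
    list(glycan = "Manb1-4Manb", carbonyl = 1, blocked = 4L),
    list(glycan = "Manb1-6Manb", carbonyl = 1, blocked = 6L),
    list(glycan = "GlcNAcb1-2Man", carbonyl = 1, blocked = 2L)
  )
  for (L in 0:3) {
    for (cs in cases) {
      expect_equal(
        package_primary_pathways(cs$glycan, L = L),
        oracle_primary_pathways(cs$carbonyl, cs$blocked, L = L),
        label = paste(cs$glycan, "L =", L)
      )
    }
  }
})

test_that("mass is conserved on every enumerated pathway", {
  for (s in c("Glcb", "Fru", "Manb1-2Manb-18O1", "Manb1-3Manb-18O1",
              "Manb1-4Manb-18O1", "GlcNAcb1-2Man", "Manb-OMe")) {
    g <- parse_glycan(s)
    total <- glycan_comp(g)
    prec <- precursor_mz(g)$mz_monoisotopic
    for (p in enumerate_pathways(g)) {
      expect_equal(comp_add(p$retained_comp, p$lost_comp), total,
                   label = paste(s, paste(p$steps, collapse = ">")))
      ion <- fragment_ion(p, g)
      expect_lt(abs(prec - ion$mz_monoisotopic - ion$neutral_loss), 1e-4)
    }
  }
})

test_that("exactly one 18O crosses each partition when one label is present", {
  g <- parse_glycan("Manb1-2Manb-18O1")
  for (p in enumerate_pathways(g)) {
    n_lost <- p$lost_comp[["O18"]]
    n_kept <- p$retained_comp[["O18"]]
    expect_equal(n_lost + n_kept, 1)
    expect_equal(p$label_retained, n_kept == 1)
  }
})

test_that("18O-labeled 1->2 disaccharide reproduces the printed fragment set", {
  sp <- predict_spectrum("Manb1-2Manb-18O1")
  expect_equal(sp$mz_nominal[sp$tier == "major"], 247L)
  expect_true(all(c(245, 275, 277, 305, 307, 337) %in% sp$mz_nominal))
  losses <- sp$neutral_loss_nominal[match(c(245, 275, 277, 305, 307, 337), sp$mz_nominal)]
  expect_equal(losses, c(122L, 92L, 90L, 62L, 60L, 30L))
  # the m4_3 + c1 route sheds the labeled C1 as CH2(18O)
  expect_true(335 %in% sp$mz_nominal)
  expect_false(sp$label_retained[sp$mz_nominal == 335])
})

test_that("a methyl glycoside has no reducing-end pathways and only those", {
  fr_ome <- fragments("Manb-OMe")
  expect_equal(sum(fr_ome$site == "reducing_end"), 0)
  expect_gt(sum(fr_ome$site == "non_reducing_end"), 0)
  expect_true(all(fr_ome$tier == "trace"))
  expect_true(all(fr_ome$rl_barrier >= 231, na.rm = TRUE))
  # the free monosaccharide has reducing-end pathways and no catalog entries
  fr_free <- fragments("Manb")
  expect_gt(sum(fr_free$site == "reducing_end"), 0)
  expect_equal(sum(fr_free$site == "non_reducing_end"), 0)
})

test_that("the linkage-to-dominant-loss map reproduces the diagnostic pattern", {
  major_losses <- function(s) {
    sp <- predict_spectrum(s)
    sort(unique(sp$neutral_loss_nominal[sp$tier == "major"]))
  }
  expect_equal(major_losses("Manb1-2Manb"), 120L)
  expect_equal(major_losses("Manb1-3Manb"), 90L)
  expect_equal(major_losses("Manb1-4Manb"), 60L)
  expect_equal(major_losses("Manb1-6Manb"), c(60L, 90L, 120L))
})

test_that("classification follows barriers, step counts and accessibility", {
  # 1->2: direct c2 (152 kJ/mol) is major; shift routes (161/172/190) minor
  fr <- fragments("Manb1-2Manb")
  major <- fr[fr$tier == "major", ]
  expect_equal(major$pathway, "RO>c2")
  expect_equal(major$rl_barrier, 152)
  shift_routes <- fr[grepl("m1_[456]", fr$pathway) & fr$stage_depth == 1, ]
  expect_true(all(shift_routes$tier == "minor"))

  # 1->3: rank-only barrier data; m1_2 route wins over lower-barrier m1_5
  # because its pathways need fewer steps
  fr3 <- fragments("Manb1-3Manb-18O1")
  expect_equal(fr3$pathway[fr3$tier == "major"], "RO>m1_2>c3")
  expect_equal(fr3$mz_nominal[fr3$tier == "major"], 277L)

  # non-reducing-end pathways are trace
  expect_true(all(fr3$tier[fr3$site == "non_reducing_end"] == "trace"))

  # classification is deterministic
  g <- parse_glycan("Manb1-4Manb")
  t1 <- vapply(classify(enumerate_pathways(g), g), `[[`, character(1), "tier")
  t2 <- vapply(classify(enumerate_pathways(g), g), `[[`, character(1), "tier")
  expect_identical(t1, t2)
})

test_that("secondary dissociation explains the two-stage losses", {
  # glucose: primary loss 60 then secondary loss 60 -> m/z 83
  fr <- fragments("Glcb")
  sec <- fr[fr$stage_depth == 2 & fr$mz_nominal == 83, ]
  expect_gt(nrow(sec), 0)
  expect_equal(unique(sec$neutral_loss_nominal), 120L)
  expect_true(any(grepl("^RO>c2>", sec$pathway)))
  # 1->4: RO -> c2 -> c4 sheds 122 in total on the labeled species
  fr4 <- fragments("Manb1-4Manb-18O1")
  s245 <- fr4[fr4$mz_nominal == 245, ]
  expect_true(any(s245$stage_depth == 2))
  expect_equal(unique(s245$neutral_loss_nominal), 122L)
  expect_true(all(s245$tier %in% c("minor", "trace")))
})

test_that("non-reducing-end catalog fragments match the printed m/z values", {
  # labeled 1->3: m/z 247 arises only from the residue not at the reducing end
  sp <- predict_spectrum("Manb1-3Manb-18O1")
  row247 <- sp[sp$mz_nominal == 247, ]
  expect_equal(row247$tier, "trace")
  expect_true(grepl("c0p3p|RO1p|RO2p", row247$pathways))
  expect_true(row247$label_retained)
})

test_that("keto-hexose dominates by loss of 90", {
  sp <- predict_spectrum("Fru")
  expect_equal(sp$neutral_loss_nominal[sp$tier == "major"], 90L)
  expect_equal(sp$mz_nominal[sp$tier == "major"], 113L)
})

test_that("GlcNAc disaccharide reproduces the MS3 stage fragments", {
  sp <- predict_spectrum("GlcNAcb1-2Man")
  expect_equal(attr(sp, "precursor_nominal"), 406L)
  expect_equal(sp$mz_nominal[sp$tier == "major"], 286L)
  minors <- sp$mz_nominal[sp$tier == "minor"]
  expect_true(all(c(316, 346) %in% minors))
})
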