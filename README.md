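# thalscreen

Evaluation and multi-criteria ranking of red-cell discriminant indices for
β-thalassemia trait (BTT) screening.

## The problem

β-thalassemia carriers are usually asymptomatic but transmit the allele;
population screening is the only way to find them before two carriers have
an affected child. The confirmatory tests (HbA2 quantitation by HPLC,
molecular studies) are too expensive to run on every sample, so screening
programs triage with arithmetic indices computed from the complete blood
count (CBC) that every hematology analyzer already produces: Hb, HCT, MCV,
MCH, MCHC, RBC and RDW. Dozens of such indices have been published — the
Mentzer index MCV/RBC < 13, Shine & Lal MCV²·MCH/100 < 1530, England &
Fraser MCV − RBC − 5·Hb < 0, and so on — each tuned to separate BTT from
its main microcytic mimic, iron deficiency anemia.

No single index wins on every performance measure: one maximises
sensitivity, another specificity or predictive value. `thalscreen`
re-implements a published evaluation design that treats index selection as
a multi-criteria decision problem: score each formula on eight
confusion-matrix measures (SE, SP, Youden index YI = SE + SP − 1,
single-operating-point AUC = (SE + SP)/2, accuracy, PPV, NPV, and the false
omission rate FOR = FN/(TN + FN), the one cost-direction criterion), drop
worse-than-chance formulae (YI < 0), and rank the rest with three MCDM
methods:

* **TOPSIS** — vector-normalised matrix, Shannon-entropy criterion
  weights, closeness C = D⁻/(D⁺ + D⁻) to the ideal solution;
* **COPRAS** — benefit/cost sums with the min-cost ratio correction,
  utility degree U = 100·Q/max Q;
* **SECA** — weights and scores determined together by maximising
  min-score minus β times the distance of the weights from
  dispersion- and correlation-based reference points, solved over the
  weight simplex.

The recommended operational rule that comes out of the analysis is a
**two-step screen**: refer a sample for confirmatory testing when
MCV ≤ 80 fl **and** the SCS_BTT linear score
0.2815·MCV + 0.2015·MCH − 0.2641·RBC − 0.1693·RDW + 0.0835·Hb
falls below 24.99.

## Worked example

Rank the 42 published formulae from the bundled published performance
table (the packaged regression fixture, so no patient data is needed):

```r
library(thalscreen)
t2 <- reference_performance_table()     # 42 formulae x 8 measures
split <- exclude_negative_yi(t2)
split$excluded$formula_id
#> rdw huber_herklotz sirachainan hameed zaghloul_1 zaghloul_2 kandhro_1
rk <- rank_formulae(split$retained)     # entropy + TOPSIS/COPRAS/SECA
rk$topsis
#> <ranking_result> TOPSIS, 35 alternatives; top 5:
#>                 rank  score
#> shine_lal          1 0.9295
#> scs_btt            2 0.9291
#> ravanbakhsh_f4     3 0.8756
#> telmissani_mchd    4 0.8081
#> bordbar            5 0.7885
rk$copras
#> <ranking_result> COPRAS, 35 alternatives; top 5:
#>                rank    score
#> scs_btt           1 100.0000
#> shine_lal         2  90.9752
#> ravanbakhsh_f4    3  83.7833
#> kerman_1          4  74.0606
#> nishad            5  70.6356
round(rk$spearman, 3)
#> topsis_copras   topsis_seca   copras_seca
#>         0.576         0.461         0.981
```

Shine & Lal leads under TOPSIS; SCS_BTT leads under COPRAS and SECA — the
two formulae a program would shortlist. Screening an unlabeled hemogram:

```r
rec <- data.frame(subject_id = "P001", hb = 10, hct = 33, mcv = 60,
                  mch = 19, mchc = 31.7, rbc = 5.5, rdw = 16)
two_step_screen(rec)
#>   subject_id mcv_gate scs_value               call
#> 1       P001     TRUE  17.39215 refer_confirmatory
```

The record passes the MCV gate (60 ≤ 80 fl) and scores 17.39 < 24.99, so
it is referred for confirmatory testing.

Synthetic labeled cohorts for end-to-end validation come from
`generate_cohort(default_group_params(), seed)` (nine diagnostic groups,
truncated multivariate normal, analyzer identities enforced) or the
deliberately separable `separable_cohort(n_pos, n_neg, seed)`.

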