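Published Shanghai Fangcang shelter-hospital case fixtures (plain text).

shili_weights.csv / shili_ranking.csv / renli_weights.csv /
renli_ranking.csv / sensitivity_cases_*.csv transcribe the printed
tables of the case study: entropy weights and TOPSIS closeness of the
22 post-screening candidates, Best-Worst-Method weights and fuzzy-TOPSIS
closeness of the 11 finalists, and the ten sensitivity weight vectors
per stage.

renli_judgments_reconstructed.csv is SYNTHETIC: the raw linguistic
judgment table behind the final ranking was published only as a
supplementary file that is not redistributed here. This stand-in was
reconstructed by exhaustive search over the seven-term vocabulary for
the assignment whose fuzzy-TOPSIS closeness best reproduces the printed
nine-decimal values (max deviation 3.9e-4 under the default engine).
Because it was fitted to the published output, agreement with that
output demonstrates internal consistency of the engine, not an
independent reproduction of the study.

The raw 22x5 Shili evaluation matrix (supplementary appendix 1) is not
redistributable and not reconstructable from the printed tables. Users
with access to the supplementary files can drop them here as
shili_matrix_moesm1.csv (id,name,category,air_access,rail_access,
road_access,hospital_km,beds) and renli_judgments_moesm2.csv
(id,name,<four criterion columns of linguistic terms>); the test suite
and shanghai_case() pick them up automatically.
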