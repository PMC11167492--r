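# Per-family parameters for the statistical potentials: contacts
# observed in structures (contacts_pdb) and added from PBM-extended
# models (contacts_pbm), the selected contacts database, scope,
# polynomial smoothing, binning, interface radius and redundancy (MSA)
# threshold. The GLOBAL row holds the totals and the general-potential
# selection. The C2H2 ZF row keeps its externally derived potential
# (db/scope not selected here).
families:
  - {family: GLOBAL,           contacts_pdb: 24651376, contacts_pbm: 762340857, db: pbm, scope: general, taylor: true,  binning: acc,  radius: 15, msa_threshold: 0.82}
  - {family: AP2,              contacts_pdb: 1194,     contacts_pbm: 3284248,   db: pbm, scope: family,  taylor: false, binning: acc,  radius: 15, msa_threshold: 0.88}
  - {family: C2H2 ZF,          contacts_pdb: 224004,   contacts_pbm: 35467680,  db: pbm, scope: family,  taylor: false, binning: acc,  radius: 30, msa_threshold: 0.94}
  - {family: DM,               contacts_pdb: 5114,     contacts_pbm: 712912,    db: pbm, scope: family,  taylor: true,  binning: acc,  radius: 22, msa_threshold: 0.92}
  - {family: E2F,              contacts_pdb: 6610,     contacts_pbm: 816150,    db: pbm, scope: family,  taylor: true,  binning: acc,  radius: 30, msa_threshold: 0.84}
  - {family: Ets,              contacts_pdb: 92384,    contacts_pbm: 26654782,  db: pbm, scope: family,  taylor: false, binning: bins, radius: 30, msa_threshold: 0.72}
  - {family: Forkhead,         contacts_pdb: 64852,    contacts_pbm: 20463990,  db: pdb, scope: family,  taylor: true,  binning: acc,  radius: 22, msa_threshold: 0.84}
  - {family: GATA,             contacts_pdb: 28524,    contacts_pbm: 7818301,   db: pbm, scope: general, taylor: false, binning: acc,  radius: 15, msa_threshold: 0.92}
  - {family: Homeodomain,      contacts_pdb: 183264,   contacts_pbm: 432353402, db: pbm, scope: family,  taylor: false, binning: acc,  radius: 22, msa_threshold: 0.84}
  - {family: IRF,              contacts_pdb: 31656,    contacts_pbm: 2285198,   db: pbm, scope: family,  taylor: false, binning: bins, radius: 22, msa_threshold: 0.88}
  - {family: Myb/SANT,         contacts_pdb: 80230,    contacts_pbm: 11300750,  db: pdb, scope: family,  taylor: true,  binning: acc,  radius: 22, msa_threshold: 0.80}
  - {family: NAC/NAM,          contacts_pdb: 15098,    contacts_pbm: 1980110,   db: pdb, scope: family,  taylor: false, binning: acc,  radius: 15, msa_threshold: 0.76}
  - {family: Nuclear receptor, contacts_pdb: 294588,   contacts_pbm: 89311996,  db: pbm, scope: family,  taylor: false, binning: acc,  radius: 22, msa_threshold: 0.96}
  - {family: Sox,              contacts_pdb: 189228,   contacts_pbm: 5088596,   db: pdb, scope: family,  taylor: true,  binning: bins, radius: 22, msa_threshold: 0.76}
  - {family: T-box,            contacts_pdb: 40904,    contacts_pbm: 6916258,   db: pbm, scope: family,  taylor: true,  binning: acc,  radius: 15, msa_threshold: 0.80}
  - {family: WRKY,             contacts_pdb: 952,      contacts_pbm: 777282,    db: pbm, scope: family,  taylor: false, binning: acc,  radius: 22, msa_threshold: 0.82}
  - {family: Zinc cluster,     contacts_pdb: 43168,    contacts_pbm: 2306230,   db: pbm, scope: family,  taylor: false, binning: acc,  radius: 15, msa_threshold: 0.82}
  - {family: bHLH,             contacts_pdb: 61656,    contacts_pbm: 13400550,  db: pbm, scope: family,  taylor: false, binning: acc,  radius: 30, msa_threshold: 0.96}
  - {family: bZIP,             contacts_pdb: 67216,    contacts_pbm: 19605124,  db: pdb, scope: family,  taylor: true,  binning: acc,  radius: 30, msa_threshold: 0.88}
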