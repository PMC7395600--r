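taxonID,parentNameUsageID,scientificName,taxonRank,datasetName,conceptNote
T0001,,ladon,concept,switchboard,complex=celastrina-ladon
T0002,,neglecta,concept,switchboard,complex=celastrina-ladon
T0003,,lucia,concept,switchboard,complex=celastrina-ladon
T0004,,echo,concept,switchboard,complex=celastrina-ladon
T0005,,humulus,concept,switchboard,complex=celastrina-ladon
T0006,,serotina,concept,switchboard,complex=celastrina-ladon
T0007,,idella,concept,switchboard,complex=celastrina-ladon
T0008,T0001,Celastrina ladon,species,NABA,holder for ladon
T0009,T0002,Celastrina ladon,species,NABA,holder for neglecta
T0010,T0003,Celastrina ladon,species,NABA,holder for lucia
T0011,T0004,Celastrina ladon,species,NABA,holder for echo
T0012,T0005,Celastrina ladon,species,NABA,holder for humulus
T0013,T0006,Celastrina ladon,species,NABA,holder for serotina
T0014,T0007,Celastrina ladon,species,NABA,holder for idella
T0015,T0001,Celastrina ladon,species,OW,
T0016,T0002,Celastrina neglecta,species,OW,
T0017,T0003,Celastrina lucia,species,OW,
T0018,T0004,Celastrina echo,species,OW,
T0019,T0005,Celastrina humulus,species,OW,
T0020,T0007,Celastrina idella,species,OW,
T0021,T0001,Celastrina ladon,species,Pelham,
T0022,T0002,Celastrina neglecta,species,Pelham,
T0023,T0003,Celastrina lucia,species,Pelham,
T0024,T0004,Celastrina echo,species,Pelham,
T0025,T0005,Celastrina humulus,species,Pelham,
T0026,T0006,Celastrina serotina,species,Pelham,
T0027,T0007,Celastrina idella,species,Pelham,
T0028,T0008,Celastrina ladon/neglecta,conglomerate,Illinois,flag: taxon concept interpretations differ across authorities in this complex; verify compatibility before combining; deviates from base: field-indistinguishable pair pooled
T0029,T0009,Celastrina ladon/neglecta,conglomerate,Illinois,flag: taxon concept interpretations differ across authorities in this complex; verify compatibility before combining
T0030,T0008,Celastrina ladon/neglecta,conglomerate,Michigan,flag: taxon concept interpretations differ across authorities in this complex; verify compatibility before combining; deviates from base: field-indistinguishable pair pooled
T0031,T0009,Celastrina ladon/neglecta,conglomerate,Michigan,flag: taxon concept interpretations differ across authorities in this complex; verify compatibility before combining
T0032,T0008,Celastrina ladon/neglecta,conglomerate,Tennessee,flag: taxon concept interpretations differ across authorities in this complex; verify compatibility before combining; deviates from base: field-indistinguishable pair pooled
T0033,T0009,Celastrina ladon/neglecta,conglomerate,Tennessee,flag: taxon concept interpretations differ across authorities in this complex; verify compatibility before combining
T0034,T0008,Celastrina ladon,species,Iowa,flag: taxon concept interpretations differ across authorities in this complex; verify compatibility before combining
T0035,T0009,Celastrina ladon,species,Iowa,flag: taxon concept interpretations differ across authorities in this complex; verify compatibility before combining
T0036,T0008,Celastrina ladon,species,Ohio,flag: taxon concept interpretations differ across authorities in this complex; verify compatibility before combining; deviates from base: splits the broad concept
T0037,T0009,Celastrina neglecta,species,Ohio,flag: taxon concept interpretations differ across authorities in this complex; verify compatibility before combining
T0038,T0015,Celastrina ladon,species,Florida,flag: taxon concept interpretations differ across authorities in this complex; verify compatibility before combining
T0039,T0016,Celastrina neglecta,species,Florida,flag: taxon concept interpretations differ across authorities in this complex; verify compatibility before combining
T0040,T0015,Celastrina ladon,species,Colorado,flag: taxon concept interpretations differ across authorities in this complex; verify compatibility before combining
T0041,T0019,Celastrina humulus,species,Colorado,flag: taxon concept interpretations differ across authorities in this complex; verify compatibility before combining
T0042,T0018,Celastrina ladon echo,subspecies,OrangeCounty,scope=ladon|lucia|echo; curated circumscription of the program's trinomial usage
T0043,T0023,Celastrina lucia,species,Cascades,flag: taxon concept interpretations differ across authorities in this complex; verify compatibility before combining
T0044,T0024,Celastrina echo,species,Cascades,flag: taxon concept interpretations differ across authorities in this complex; verify compatibility before combining
T0045,T0024,Celastrina echo,species,MPG,
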