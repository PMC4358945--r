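>P01966 HBA_BOVIN Hemoglobin subunit alpha (Bos taurus)
MVLSAADKGNVKAAWGKVGGHAAEYGAEALERMFLSFPTTKTYFPHFDLSHGSAQVKGHG
AKVAAALTKAVEHLDDLPGALSELSDLHAHKLRVDPVNFKLLSHSLLVTLASHLPSDFTP
AVHASLDKFLANVSTVLTSKYR
>P02070 HBB_BOVIN Hemoglobin subunit beta (Bos taurus)
MLTAEEKAAVTAFWGKVKVDEVGGEALGRLLVVYPWTQRFFESFGDLSTADAVMNNPKVK
AHGKKVLDSFSNGMKHLDDLKGTFAALSELHCDKLHVDPENFKLLGNVLVVVLARNFGKE
FTPVLQADFQKVVAGVANALAHRYH
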