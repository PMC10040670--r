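>synthetic_SbCA3_standin 448aa synthetic sequence constructed to match the reported SbCA3 (KXG32970) MW 48986.93 Da and pI 8.74; NOT the real protein
GRVKFAKFASQVIEIPPRRQYGQSPHNRNGEIRGRFNSQKSFPPVATALIKAFIAYSLLM
SPWPLVIHNRVIFKLKQTDLDFATATINPSLPNTQFDIPCIQAKTIQQQVHHLIFVFSGV
FTTVLDGGFWKENQMPMAGMLSPQNSGLDTKGQNSAPDFNKTKIQPILIIRHETQVVKYP
QWDSPVGEPSHGHGDGNGRQFEGDGKPNNNDNIGKVAAEIFDMNQLQSAEALVGPYPIGI
KYIGGLEAVWSGYPAQPGTPDIINMKILGFQFLNGGGIGGPFQFNSCEEFFGFKFPSIVK
TYKEDSTSADAEQFKLGQEARQIPIIVITHRALSNKTGGEGGERCITDLIAAVPPGVLVK
TIADALGYPAQNQDKYFTPKVVFQGIKIIIGNKGCTLQSTSDGASSPNMQCLQKFYASPV
QFIPIFTAVDNGRFDPAPLSGCNPRVNL
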